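---
title: "How wsianon removes sensitive data while preserving native slide formats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How wsianon removes sensitive data while preserving native slide formats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsianon)
```

## The problem

A whole-slide image is a gigapixel pyramid of tissue tiles plus baggage:
a photograph of the slide label (usually carrying the case ID as text or
barcode), a macro overview photo of the glass slide, and metadata written
by the scanner — serial numbers, acquisition timestamps, operator
accounts. The label is directly identifying; the acquisition metadata is
indirectly identifying, because a scanner serial plus a timestamp narrows
a slide to one institution and a treatment window. De-identification for
research and teaching therefore has to remove both groups, and it has to
do so *inside* the proprietary vendor format, because the consuming
software (vendor viewers, OpenSlide-style readers) only speaks that
format.

`wsianon` treats this as a binary-patching problem. Vendor formats
allocate values at fixed offsets with fixed lengths; rewriting a file
moves offsets and breaks it, but overwriting bytes in place cannot. Every
operation in the package is therefore a patch at a known offset that
keeps every other byte where it was.

## The anonymization ladder

Runs are graded on a four-step ladder, reported as `achieved_level`:

* **I** — only the filename was scrubbed (files are renamed to a
  content-hash by default, since filenames often embed case IDs);
* **II** — label/macro directories were *dereferenced* but their pixel
  data still exists in the file (cheap to undo, hence insufficient);
* **III** — the label image content was physically destroyed;
* **IV** — level III plus neutralization of every registry metadata
  occurrence in both categories (subject-related and
  acquisition-related). This is the default configuration.

The mapping is mechanical: IV requires a blanked label (on NDPI/BIF the
blanked combined label+macro counts) and replaced counts covering every
occurrence found; III requires the blanked label; II requires only
unlink-type actions.

## TIFF-family mechanics

SVS, NDPI and BIF are TIFF dialects: a header (byte order, version 42 or
43, first-IFD pointer) and a linked chain of Image File Directories.
Each IFD is an entry count, a sorted table of fixed-size tag entries
(12 bytes classic / 20 bytes BigTIFF, with a 4/8-byte inline value
field), and a next-IFD pointer. Three primitives cover everything:

1. **Blob overwrite** (`overwrite_blob`, `blank_image`). Strips/tiles are
   located from the strip/tile offset and byte-count tags. A blank image
   is encoded in the codec the directory declares — uncompressed fill,
   LZW (encoded by libtiff and extracted from a one-strip scratch TIFF),
   Deflate (a zlib stream from `memCompress`), or baseline JPEG — and
   written over the region; if it is shorter, the byte-count tag is
   rewritten and the slack zero-filled, so the original bytes are gone
   even from the unreferenced tail. The file never grows. Blank means
   white (inverted for WhiteIsZero photometric interpretation) so viewers
   show an obviously empty image. Codecs the package cannot re-encode
   (e.g. vendor JPEG2000 variants) are handled by zeroing the raw blobs
   and force-unlinking the directory: confidentiality wins over
   decodability for that one directory, and a warning says so.
2. **IFD unlink** (`unlink_ifd`). The predecessor's next-IFD pointer (or
   the header's first-IFD field, for the first directory) is rewritten to
   point past the victim; unlinking the last directory writes a null
   pointer. The directory's bytes remain physically present — which is
   exactly why blanking comes first.
3. **Same-length string replacement** (`replace_tag_string`,
   occurrence-level span replacement). ASCII tag values and `Key = Value`
   fields inside Aperio-style descriptions (or `attr="value"` spans in
   Ventana's XML description) are overwritten with a content-free run of
   one printable character of *identical byte length*, preserving every
   NUL byte bit-exactly, so tag counts, offsets and file size are all
   unchanged.

Which IFD is the label and which tags are sensitive is vendor knowledge,
kept in per-vendor registries (`vendor_profile`): SVS marks associated
images with "label"/"macro" words in their descriptions and stores
metadata as `Key = Value` description fields; NDPI encodes directory
roles in its SourceLens private tag (−1 is the combined label+macro) and
metadata in private tags (65427 barcode reference, 65442 serial) plus
standard DateTime/Artist; BIF uses an iScan XML description. Scanner
software revisions move these fields, so registries are extensible at
run time from a JSON profile file without code changes. NDPI and BIF
store label and macro as one combined image; a `keep_macro` request
there is honored as "blank anyway and warn", never as "keep".

## Mirax and iSyntax

A Mirax slide is a directory: `Slidedat.ini` (INI text describing the
layer hierarchy), `Index.dat` (a binary table mapping layers to
(file, offset, length) spans) and numbered `.dat` payload files. Label
and macro blobs are zero-filled in place inside the `.dat` files;
`Slidedat.ini` is the one file that is rewritten rather than patched
(atomically, write-temp-then-rename), because removing layer references
changes line lengths — afterwards no string in it names a removed layer.
The real `Index.dat` layout is undocumented and varies across Mirax
software versions, so the package implements one explicit synthetic
layout tied to the declared `SLIDE_VERSION` and refuses any other
version with a precise unsupported-version error rather than guessing —
failing closed is the only safe behavior for a confidentiality tool. The
thumbnail layer is treated as macro-family, since overview photos can
capture the label edge.

An iSyntax file is an XML header (typed attribute nodes, base64-encoded
label and macro images) terminated by an EOT byte, followed by the
binary tissue codestream. The vendor SDK requires the node skeleton to
survive, so nodes are never added or removed. String values are replaced
at identical length; datetimes by an epoch placeholder in the same
calendar format; range-constrained numerics by their lower bound;
unknown datatypes on sensitive keys fail closed. Label/macro payloads
are decoded (PNG or JPEG sniffed from magic bytes), re-encoded as a
blank image of the same dimensions and codec, and padded with whitespace
— legal in both XML text and base64 — to occupy the identical span.
Because every replacement is no longer than the original, the header
span never changes and the binary body is untouched; the full-file
rewrite fallback that a growing header would need is deliberately not
implemented, and a capacity error would surface if that invariant ever
broke.

## Workflow, atomicity, naming

`anonymize()` runs detect → rename → (optional backup) → locate → patch.
All patching happens on a staged copy that is moved into place only on
success, so a failure leaves either the untouched original or a complete
output, never a half-patched file; `in_place = TRUE` then replaces the
original. The default output name is the first 12 hex characters of the
input's MD5 — original filenames frequently embed case IDs, so they
never survive by default. Identical input bytes and configuration yield
byte-identical output, and re-running on an already-anonymized file is a
byte-level no-op.

## What the fixtures emulate — and what they do not

No vendor slide can ship with the package, so the `make_fixture` module
fabricates minimal structural replicas: 3–4 IFD TIFF pyramids (tiled and
stripped directories, inline and out-of-line tags, one JPEG and one
uncompressed associated image, classic and BigTIFF, both byte orders
exercised in tests, and an optional sparse >4 GiB BigTIFF to prove
64-bit offsets), a Mirax directory set in the synthetic index layout,
and an iSyntax header over an opaque random body. Every fixture plants
unique ≥6-byte sensitive payloads (case ID, barcode, serial, datetime,
operator, label/macro pixel signatures) recorded in a manifest; the
post-run oracle is an exhaustive byte scan for those payloads over whole
files, unreferenced regions included. Slide dimensions are tens of
pixels rather than gigapixels — byte-level patching is size-independent,
so small files exercise the identical code paths; what fixtures do *not*
emulate is real vendors' full tag inventories, vendor-specific codecs
(JPEG2000 paths are exercised only through the zero-and-unlink
fallback), multi-version Mirax index layouts, or the proprietary iSyntax
body. Passing tests therefore demonstrate the mechanics are correct on
faithful structures, not that every field of every scanner-software
revision is registered — which is why profiles are run-time extensible.

## Numerical and policy choices

* Fixture payload values and pixel noise derive from a single integer
  seed; generation is byte-deterministic.
* The replacement character defaults to `"X"`; any printable ASCII
  character is accepted.
* Blank JPEG quality is 0.9; for a uniform image the decoded result is
  exactly uniform, which the tests assert via zero pixel variance in an
  independent reader.
* The acceptance script runs six formats end-to-end, the full 2⁵
  unlink-subset oracle on a five-directory chain, and 1,000 randomized
  string-tag replacements (lengths 1–40, with and without NUL
  terminators, inline and out-of-line) — sizes chosen to exercise every
  branch of the entry layout while completing in seconds.

## Known limitations

* Registries cover common, publicly documented fields; a scanner
  revision can introduce new sensitive tags that must be added via a
  profile file (the scan oracle only checks payloads the manifest knows
  about).
* Tissue pixels are out of scope: a slide can still be matched to its
  physical twin by image content; no file-level tool can prevent that.
* Only 8-bit samples are re-encoded as blank images; exotic bit depths
  fall back to zero-and-unlink.
* OCR of burned-in label text inside the *tissue* region is not
  attempted.
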