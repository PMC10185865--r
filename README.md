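# wsianon

Structure-preserving anonymization of whole-slide images (WSI) in R.

Digitized pathology slides carry more than tissue: the scanner photographs
the slide label (case ID, barcode) and an overview ("macro") image, and the
file metadata records scanner serial numbers, acquisition dates/times and
operator names. A serial number plus a timestamp can pin a slide to an
institution and admission period, so sharing slides for research or teaching
requires removing **both** subject-related and acquisition-related data —
while keeping the file readable by the proprietary viewers and open-source
readers that consume these vendor formats.

`wsianon` does this without converting or rewriting the file. It patches
bytes at fixed offsets so that no internal pointer ever moves:

- **Label/macro images** are overwritten with blank images encoded in the
  compression the directory declares (none, LZW, Deflate, JPEG), then the
  directory is *unlinked* from the TIFF IFD chain by rewriting its
  predecessor's next-IFD pointer (or the header's first-IFD field), with the
  last directory terminated by a null pointer.
- **Metadata strings** are replaced by content-free strings of *identical
  byte length* (NUL bytes preserved bit-exactly), because tag values live in
  fixed allocations whose growth would invalidate the format.
- **Mirax** slide sets get their label/macro blobs zero-filled inside the
  `.dat` files (located via `Index.dat`) and `Slidedat.ini` atomically
  rewritten with no reference to the removed layers.
- **iSyntax** files get typed XML attribute values replaced under their
  datatype/range constraints and base64 label/macro payloads substituted by
  blank images of the same decoded dimensions and codec, padded so the
  header span and the binary body are untouched.

Supported formats: Aperio/Leica SVS (classic TIFF and BigTIFF), Hamamatsu
NDPI, Ventana BIF, 3DHistech Mirax (`.mrxs` + data directory), Philips
iSyntax, plus vendor-less generic TIFF (fail-soft with a warning). On NDPI
and BIF the label and macro are one combined image that cannot be kept
separately; `keep_macro` there blanks it anyway and warns.

Results are reported on a four-step ladder: **I** filename scrubbed, **II**
images dereferenced only, **III** label image content destroyed, **IV**
label destroyed *and* all subject- and acquisition-related metadata
neutralized (the default).

## Worked example

No vendor files can be redistributed, so the package fabricates minimal,
structurally faithful fixtures with a manifest of planted sensitive
payloads:

```r
library(wsianon)

fx <- make_fixture("svs", tempdir(), seed = 7)
fx$manifest[, c("role", "value")]
#>             role               value
#> 1        CASE_ID       CASE-8582-575
#> 2        BARCODE          BC51252231
#> 3 SCANNER_SERIAL           SN-573922
#> 4   ACQ_DATETIME 2021:08:08 21:46:07
#> 5       OPERATOR       techuser-1570
#> 6   LABEL_PIXELS     LBLSIG-82962315
#> 7   MACRO_PIXELS     MACSIG-72016403

rep <- anonymize(fx$paths[["main"]], wsi_config())
rep
#> <wsi_report> APERIO_SVS -> level IV
#>   input:  /tmp/.../slide_svs_7.svs
#>   output: /tmp/.../193df4caeddd.svs
#>   10 action(s), 4193 bytes modified

nrow(scan_for_payloads(rep$output_path, fx$manifest))
#> [1] 0
```

The report lists every action (blank_image, unlink_ifd, replace_metadata,
rename) with the bytes it modified; `achieved_level` of `"IV"` means the
label and macro were blanked and every registry metadata occurrence in both
categories neutralized. The exhaustive byte scan — which searches the whole
file, including regions no directory references any more — finds none of
the planted payloads. The output still opens in `tiff::readTIFF()`.

A command-line front end with the same options is installed at
`system.file("scripts", "wsianon", package = "wsianon")`:

```sh
wsianon anonymize slide.svs --keep-macro --report json
wsianon check slide.ndpi
wsianon fixtures make --format svs --seed 7 --out /tmp/fx
```

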