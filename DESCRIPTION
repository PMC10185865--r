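Package: wsianon
Title: Structure-Preserving Anonymization of Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: De-identifies whole-slide images (WSI) from common pathology
    slide scanners while keeping the files readable in their native,
    proprietary formats. Detects the vendor format (Aperio/Leica SVS,
    Hamamatsu NDPI, Ventana BIF, 3DHistech Mirax, Philips iSyntax, generic
    TIFF), then patches files in place: label and macro images are
    overwritten with blank encoded images and their directories unlinked
    from the TIFF IFD chain, and sensitive metadata strings (case IDs,
    barcodes, scanner serials, acquisition dates, operator names) are
    replaced by content-free strings of identical byte length so that no
    offset in the file moves. Includes a fixture generator that fabricates
    minimal, structurally faithful slide files with a manifest of planted
    sensitive payloads, and a byte-scan oracle used to verify that no
    sensitive payload survives anonymization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    jpeg,
    png,
    tiff,
    xml2,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
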