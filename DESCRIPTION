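Package: stcontacts
Title: Spatiotemporal Analysis of GPCR-G Protein Interface Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects per-frame sidechain-sidechain contacts between a G
    protein-coupled receptor (GPCR) and the Galpha subunit of its bound G
    protein across molecular dynamics trajectory frames, using five geometric
    criteria (salt bridge, hydrogen bond, van der Waals, pi-stacking,
    cation-pi).  Contacts are keyed by generic residue numbers (GPCRdb and
    common G protein numbering), one-hot encoded into per-frame binary
    fingerprints, and classified by temporal persistence into subfamily
    specific and common interface contacts.  A linear discriminant model over
    the fingerprints ranks contact pairs by a composite of discriminant
    weight and mean class frequency, yielding a spatiotemporal code for G
    protein coupling selectivity, and a weighted promiscuity index summarises
    multi-dataset coupling tables.  Includes generators for toy receptor
    complexes and class-structured synthetic fingerprints so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
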