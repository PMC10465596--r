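Package: alcircuit
Title: Connectomic and Physiological Analysis of Antennal Lobe Interneuron Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of neuropeptidergic local-interneuron
    ensembles in glomerular olfactory networks. Provides readers and validators
    for skeleton (SWC), triangle-mesh (OBJ) and delimited synapse/annotation
    tables; synthetic-connectome, clone-innervation-matrix and fluorescence-trace
    generators with planted ground truth; arbor morphometry (dotprops, NBLAST
    similarity, synapse flow centrality, axon-dendrite segregation index);
    mesh-based synapse-to-glomerulus assignment with intraglomerular
    input:output ratio, partner demographics and transmitter-polarity
    breakdowns; staged candidate filtering with per-stage accounting;
    binary co-innervation correlation statistics, Ward clustering, innervation
    frequency and coupon-collector sampling design; and calcium-imaging
    dF/F, peak and Simpson-rule AUC response metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
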