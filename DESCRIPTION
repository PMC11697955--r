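Package: gapassr
Title: Auditory EEG Biomarkers: ERPs, Single-Trial Power and 40 Hz Gap-ASSR Phase Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for developmental mouse EEG biomarkers of auditory
    hypersensitivity and temporal processing. Generates gap-in-noise auditory
    steady-state response (gap-ASSR) and broadband noise-burst stimulus schedules,
    forward-simulates two-channel (auditory and frontal cortex) EEG cohorts with
    configurable genotype and treatment effect structure, and implements the full
    measurement chain: epoching with baseline correction and detrending, P1/N1/P2
    event-related potential peak measurement, a dynamic complex Morlet wavelet
    transform with amplitude (Gabor) normalization and a sigmoidal
    cycles-per-frequency rule, single-trial power (STP) and inter-trial phase
    clustering (ITPC) maps, cluster-based permutation tests for time-frequency
    group differences, and group statistics (exact Mann-Whitney with Holm-Sidak
    adjustment, mixed repeated-measures ANOVA with Greenhouse-Geisser correction
    and Sidak post hoc contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
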