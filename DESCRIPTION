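Package: symdrift
Title: Stochastic Frequency Dynamics of Maternally Transmitted Endosymbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-generation models of facultative, maternally transmitted
    endosymbionts (such as Wolbachia) in finite host populations. Implements
    the deterministic frequency recursion with imperfect maternal transmission,
    host fitness effects, and cytoplasmic incompatibility, together with its
    equilibria and stability analysis; a binomial-sampling stochastic engine
    analogous to a haploid Wright-Fisher model, including low-transmitter
    subgroups and log-normally fluctuating fitness; a batch replicate and
    parameter-grid runner with burn-in trimming and pooled summaries; an
    individual-based oracle simulator for validation; and configuration,
    CSV, and manifest input/output with full seed provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
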