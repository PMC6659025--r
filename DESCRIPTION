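Package: finscope
Title: Size- and Trait-Based Thermal Performance of Fish Under Coupled
    Energy and Oxygen Budgets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ecophysiological simulator of fish thermal performance that
    couples a size-based energy budget (Holling type-II feeding, standard and
    active metabolism with Arrhenius temperature scaling) to an oxygen budget
    (temperature-dependent maximum oxygen supply and ambient dissolved
    oxygen), and lets individuals choose their foraging activity by Gilliam's
    rule -- maximizing net energy gain over mortality -- subject to a
    non-negative aerobic scope. On top of the instantaneous rates it
    integrates growth through ontogeny with a maturation reaction norm,
    accumulates survival, and evaluates lifetime reproductive output (R0) as
    a fitness measure across temperatures, food levels and slow/fast
    life-history trait presets, with or without a dome-shaped oxygen supply.
    Results are returned as tidy tibbles with ggplot2 autoplot methods and a
    small command-line interface for scenario sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
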