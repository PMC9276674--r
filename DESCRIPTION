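Package: mhode
Title: Moving-Horizon Discovery of Sparse Governing Differential Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers sparse, possibly nonlinearly parameterized ordinary
    differential equations from noisy state and input time series. A candidate
    dictionary of basis functions is fitted on sliding data windows by solving
    a collocation-discretized dynamic nonlinear program (Lagrange-Radau
    orthogonal collocation on finite elements), and terms are pruned by
    coefficient-of-variation thresholding across windows. Includes adaptive
    Savitzky-Golay smoothing, stationarity and Granger-causality screening,
    ordinary-least-squares initialization with coefficient bounds, canonical
    benchmark systems (Lotka-Volterra, van der Pol, Brusselator, Lorenz, and a
    non-isothermal CSTR with an Arrhenius rate term), and evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    Matrix,
    signal,
    lmtest,
    deSolve,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
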