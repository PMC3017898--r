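#' Figure presets for the invasion simulation study
#'
#' The named parameter sets of the simulation study. All presets share
#' the base values `dn = dm = 0.001`, `alpha = 0.1`, `epsilon = 0.01`;
#' they differ in variant, haptotaxis strength `gamma`, ECM degradation
#' rate `eta`, proliferation/renewal rates, MDE decay, and (fig15) the
#' inhibitor coefficients. Grids: `N = 43` (45 points) for fig5, `N = 30`
#' (32 points) otherwise.
#'
#' @return A named list; each entry has `variant`, `params`
#'   (an `invasion_params`), and `N`.
#' @examples
#' names(invasion_presets())
#' invasion_presets()$fig1$params$gamma
#' @export
invasion_presets <- function() {
  base <- function(variant, N = 30L, ...) {
    list(variant = variant,
         params = invasion_params(dn = 0.001, dm = 0.001, alpha = 0.1,
                                  epsilon = 0.01, ...),
         N = as.integer(N))
  }
  list(
    fig1  = base("basic", gamma = 0.005, eta = 10, beta = 0),
    fig3  = base("basic", gamma = 0.01,  eta = 10, beta = 0),
    fig5  = base("basic", gamma = 0.02,  eta = 20, beta = 0, N = 43L),
    fig7  = base("proliferation", gamma = 0.005, eta = 10, beta = 0.07,
                 mu1 = 0.1, mu2 = 0.5),
    fig8  = base("proliferation", gamma = 0.005, eta = 10, beta = 0.07,
                 mu1 = 0.5, mu2 = 0.1),
    fig9  = base("saturating", gamma = 0.005, eta = 10, beta = 0.07,
                 mu1 = 0.1, mu2 = 0.5),
    fig10 = base("saturating", gamma = 0.005, eta = 10, beta = 0.07,
                 mu1 = 0.5, mu2 = 0.1),
    fig11 = base("proliferation", gamma = 0.01, eta = 10, beta = 0.07,
                 mu1 = 0.1, mu2 = 0.5),
    fig12 = base("proliferation", gamma = 0.01, eta = 10, beta = 0.07,
                 mu1 = 0.5, mu2 = 0.1),
    fig13 = base("saturating", gamma = 0.01, eta = 10, beta = 0.07,
                 mu1 = 0.1, mu2 = 0.5),
    fig14 = base("saturating", gamma = 0.01, eta = 10, beta = 0.07,
                 mu1 = 0.5, mu2 = 0.1),
    fig15 = base("inhibitor", gamma = 0.005, eta = 10, beta = 0.07,
                 mu1 = 0.5, mu2 = 0.1, du = 0.001,
                 theta = 0.05, xi = 0.03, rho = 0.07)
  )
}

#' Fetch one preset by name
#'
#' @param name Preset name, e.g. `"fig1"`.
#' @return A list with `variant`, `params`, `N`.
#' @export
preset <- function(name) {
  tab <- invasion_presets()
  if (!name %in% names(tab)) {
    stop("unknown preset `", name, "`; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  tab[[name]]
}
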