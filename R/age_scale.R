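#' Species maximum-lifespan registry
#'
#' Maximum lifespans (years) used to express chronological age as a
#' fraction of lifespan before the negative log-log transform. Defaults:
#' human 120 years, mouse 4 years.
#'
#' @param overrides optional named numeric vector of species -> lifespan
#'   (years) added to, or replacing entries of, the default registry.
#' @return named numeric vector of lifespans in years.
#' @export
lifespan_registry <- function(overrides = NULL) {
  reg <- c(human = 120, mouse = 4)
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)), all(overrides > 0))
    reg[names(overrides)] <- overrides
  }
  reg
}

#' Lifespan-scaled age transform
#'
#' Maps chronological age to `-log(-log(age / maximum lifespan))`
#' (natural logarithms), aligning developmental and aging time points
#' between species: equal relative ages map to equal scaled ages, and the
#' transform stretches both ends of life relative to mid-life.
#'
#' Ages at or beyond the domain boundaries (0 and the species lifespan)
#' are clamped inward by `eps` (default one day) with a warning; real
#' sample sheets contain age-0 newborns.
#'
#' @param age_years chronological age(s) in years.
#' @param species character vector (recycled) naming species in the registry.
#' @param registry lifespan registry, see [lifespan_registry()].
#' @param eps clamping margin in years.
#' @return scaled ages (unitless reals).
#' @seealso [unscale_age()] for the exact inverse.
#' @export
scale_age <- function(age_years, species, registry = lifespan_registry(),
                      eps = 1 / 365.25) {
  stopifnot(is.numeric(age_years))
  L <- registry[as.character(species)]
  abort_if(anyNA(L), "unknown species in lifespan registry")
  L <- rep_len(unname(L), length(age_years))
  bad <- age_years <= 0 | age_years >= L
  if (any(bad)) {
    warning(sum(bad), " age(s) outside (0, lifespan); clamped by eps")
    age_years <- pmin(pmax(age_years, eps), L - eps)
  }
  -log(-log(age_years / L))
}

#' Invert the lifespan-scaled age transform
#'
#' @param scaled scaled age(s).
#' @inheritParams scale_age
#' @return age in years: `lifespan * exp(-exp(-scaled))`.
#' @export
unscale_age <- function(scaled, species, registry = lifespan_registry()) {
  L <- registry[as.character(species)]
  abort_if(anyNA(L), "unknown species in lifespan registry")
  rep_len(unname(L), length(scaled)) * exp(-exp(-scaled))
}
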