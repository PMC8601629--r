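#' Hill regulation function
#'
#' `hill(c, K, n) = c^n / (K^n + c^n)`, evaluated in log space so that the
#' near-step regime `|n| = 100` used by the threshold circuits is numerically
#' stable. Monotone increasing in `c` for `n > 0` (activation), decreasing
#' for `n < 0` (inhibition), bounded in `[0, 1]`, and equal to 1/2 at
#' `c = K`. The convention `n = 0` means "does not participate" and returns
#' exactly 1 (not the literal `c^0/(K^0 + c^0) = 1/2`, which would halve
#' rates spuriously).
#'
#' With a zero threshold (`K = 0`, which can arise when a growth threshold is
#' regulated down to its clamp), an inhibitor yields 0 and an activator 1 for
#' any `c > 0`; at the degenerate point `c = K = 0` an inhibitor yields 0.
#'
#' @param c concentration(s), >= 0. Vectorized.
#' @param K threshold(s), >= 0. Vectorized (recycled against `c`).
#' @param n Hill exponent; magnitude 100 by convention in the named schemes.
#' @return value(s) in `[0, 1]`.
#' @examples
#' hill(1, 1, 100)        # 0.5
#' hill(0, 1, -100)       # 1: absent inhibitor, no inhibition
#' hill(1.1, 1, -100)     # ~7.3e-5: just above threshold, strongly inhibited
#' @export
hill <- function(c, K, n) {
  if (any(c < 0)) stop("negative concentration")
  if (any(K < 0)) stop("negative threshold")
  if (length(n) != 1) stop("n must be a single exponent")
  if (n == 0) return(rep(1, length(c)))
  out <- stats::plogis(n * (log(c) - log(rep(K, length.out = length(c)))))
  # c = K = 0: the log-ratio is NaN; resolve by the inhibitor/activator limit
  bad <- is.nan(out)
  if (any(bad)) out[bad] <- if (n < 0) 0 else 1
  out
}

#' Secretion regulation link
#'
#' Declares that `regulator` gates the secretion of the chemical owning this
#' link: the secretion rate is multiplied by `hill(c_regulator, Ks, n)`.
#' Negative `n` (the default) means the regulator inhibits secretion, so the
#' chemical is only produced where the regulator is below `Ks`.
#'
#' @param regulator name of the regulating chemical.
#' @param Ks rescaled secretion threshold, > 0.
#' @param n Hill exponent (default -100, the threshold regime).
#' @export
secretion_link <- function(regulator, Ks = 1, n = -100) {
  stopifnot(is.character(regulator), Ks > 0)
  structure(list(regulator = regulator, Ks = Ks, n = n),
            class = "secretion_link")
}

#' Growth regulation link
#'
#' Declares that `regulator` gates the cell growth rate through
#' `hill(c_regulator, Kg_eff, n)`. Negative `n` makes it a growth inhibitor
#' (growth stops above the threshold), positive an activator. Threshold
#' modifiers implement growth-threshold regulation: the effective threshold
#' is `Kg * max(1 - sum(a_m * c_m), 0)` over the modifiers, clamped at 0
#' because a negative concentration threshold is meaningless.
#'
#' @param regulator name of the growth-regulating chemical.
#' @param Kg baseline rescaled growth threshold (1 after rescaling by the
#'   reference growth threshold).
#' @param n Hill exponent (default -100: inhibitor).
#' @param modifiers list of `list(chemical = , a = )` threshold modifiers.
#' @export
growth_link <- function(regulator, Kg = 1, n = -100, modifiers = list()) {
  stopifnot(is.character(regulator), Kg > 0)
  structure(list(regulator = regulator, Kg = Kg, n = n, modifiers = modifiers),
            class = "growth_link")
}

#' A secreted chemical
#'
#' @param name chemical identifier.
#' @param mu0 baseline effective (rescaled) secretion rate, >= 0.
#' @param gamma_r rescaled degradation ratio (1 for the reference chemical).
#' @param secretion_links list of [secretion_link()]s gating this chemical's
#'   secretion.
#' @param secretion_max optional `list(regulator = , b = )` with `b <= 0`:
#'   scales the maximum secretion rate by `max(1 + b * c_regulator, 0)`,
#'   letting the regulator tune how strongly this chemical is produced where
#'   it is produced at all.
#' @export
chemical <- function(name, mu0, gamma_r = 1, secretion_links = list(),
                     secretion_max = NULL) {
  stopifnot(is.character(name), mu0 >= 0, gamma_r > 0)
  if (!is.null(secretion_max)) {
    stopifnot(!is.null(secretion_max$regulator), secretion_max$b <= 0)
  }
  structure(list(name = name, mu0 = mu0, gamma_r = gamma_r,
                 secretion_links = secretion_links,
                 secretion_max = secretion_max),
            class = "chemical")
}

#' Regulatory circuit
#'
#' A set of chemicals plus growth-regulation links. Secretion dependencies
#' must form a directed acyclic graph (every scheme considered here is
#' feedforward); cyclic circuits are rejected.
#'
#' @param chemicals list of [chemical()]s.
#' @param growth_links list of [growth_link()]s.
#' @return object of class `circuit` with a stored topological order.
#' @export
circuit <- function(chemicals = list(), growth_links = list()) {
  names(chemicals) <- vapply(chemicals, `[[`, "", "name")
  nm <- names(chemicals)
  if (anyDuplicated(nm)) stop("duplicate chemical names")
  deps <- lapply(chemicals, function(ch) {
    d <- vapply(ch$secretion_links, `[[`, "", "regulator")
    if (!is.null(ch$secretion_max)) d <- c(d, ch$secretion_max$regulator)
    unique(d)
  })
  for (ch in chemicals) {
    for (d in deps[[ch$name]])
      if (!d %in% nm) stop("unknown regulator '", d, "' for chemical '", ch$name, "'")
  }
  for (gl in growth_links) {
    if (!gl$regulator %in% nm)
      stop("unknown growth regulator '", gl$regulator, "'")
    for (m in gl$modifiers)
      if (!m$chemical %in% nm)
        stop("unknown threshold modifier '", m$chemical, "'")
  }
  # Kahn topological sort of the secretion-dependency graph
  order <- character(0)
  remaining <- nm
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(x)
      all(deps[[x]] %in% order), TRUE)]
    if (!length(ready))
      stop("cyclic secretion dependencies are not supported: ",
           paste(remaining, collapse = ", "))
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(chemicals = chemicals, growth_links = growth_links,
                 topo_order = order),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("<circuit> %d chemical(s): %s; %d growth link(s)\n",
              length(x$chemicals), paste(names(x$chemicals), collapse = ", "),
              length(x$growth_links)))
  invisible(x)
}

# coerce concentrations to a matrix with one named column per chemical
conc_matrix <- function(circuit, conc) {
  nm <- names(circuit$chemicals)
  if (length(nm) == 0)
    return(matrix(0, if (is.matrix(conc)) nrow(conc) else 1, 0))
  if (is.matrix(conc)) {
    if (!all(nm %in% colnames(conc)))
      stop("missing concentration column(s): ",
           paste(setdiff(nm, colnames(conc)), collapse = ", "))
    conc[, nm, drop = FALSE]
  } else {
    if (!all(nm %in% names(conc)))
      stop("missing concentration entry for: ",
           paste(setdiff(nm, names(conc)), collapse = ", "))
    matrix(conc[nm], 1, dimnames = list(NULL, nm))
  }
}

#' Local secretion rate of a chemical
#'
#' Composes the baseline rate, the secretion-maximum regulation
#' `max(1 + b * c_reg, 0)` and the Hill factors of all secretion links:
#' `mu = mu0 * max(1 + b * c_reg, 0) * prod_j hill(c_j, Ks_j, n_j)`.
#'
#' @param circuit a [circuit()].
#' @param name the secreted chemical's name.
#' @param conc named concentration vector, or a matrix with one named column
#'   per chemical and one row per evaluation point.
#' @return secretion rate(s), >= 0 (one per row of `conc`).
#' @export
secretion_rate <- function(circuit, name, conc) {
  ch <- circuit$chemicals[[name]]
  if (is.null(ch)) stop("unknown chemical '", name, "'")
  cm <- conc_matrix(circuit, conc)
  mu <- rep(ch$mu0, nrow(cm))
  if (!is.null(ch$secretion_max))
    mu <- mu * pmax(1 + ch$secretion_max$b * cm[, ch$secretion_max$regulator], 0)
  for (sl in ch$secretion_links)
    mu <- mu * hill(cm[, sl$regulator], sl$Ks, sl$n)
  unname(mu)
}

#' Local growth rate
#'
#' Product of the Hill factors of all growth links, each evaluated at its
#' effective threshold `Kg * max(1 - sum(a * c_modifier), 0)`. With the
#' near-step exponents of the named schemes this approximates the indicator
#' function of the growth zone; the maximum growth rate is 1 (it sets the
#' time unit of the simulation).
#'
#' @inheritParams secretion_rate
#' @return growth rate(s) in `[0, 1]`.
#' @export
growth_rate <- function(circuit, conc) {
  cm <- conc_matrix(circuit, conc)
  g <- rep(1, nrow(cm))
  for (gl in circuit$growth_links) {
    red <- rep(0, nrow(cm))
    for (m in gl$modifiers) red <- red + m$a * cm[, m$chemical]
    Keff <- gl$Kg * pmax(1 - red, 0)
    g <- g * hill(cm[, gl$regulator], Keff, gl$n)
  }
  unname(g)
}

#' Named regulatory schemes
#'
#' Builds the regulatory circuits studied with this model:
#' \describe{
#' \item{`none`}{no chemicals; growth rate 1 everywhere (uniform growth,
#'   cluster circularizes).}
#' \item{`single_inhibitor`}{one growth inhibitor X secreted at constant
#'   rate `mu_X`; the growth zone is the region `c_X <= 1`. Grows a
#'   constant-width rod from a tip-localized growth zone.}
#' \item{`two_inhibitors`}{X as above, plus a second growth inhibitor Y
#'   secreted at rate `mu_Y0` only where `c_X < Ks` (X inhibits Y's
#'   secretion). Can split the growth zone and grow up to three
#'   protrusions.}
#' \item{`threshold_regulator`}{growth inhibitor X plus a growth-threshold
#'   regulator Y (secreted where `c_X < Ks`, optionally with secretion
#'   maximum scaled by `max(1 + b * c_X, 0)`, `b <= 0`). Y lowers X's
#'   effective growth threshold, `Kg_eff = max(1 - c_Y, 0)`, narrowing the
#'   protrusion over time into a cone that stops growing by itself.}
#' \item{`activator_s2`}{Y secreted constitutively at rate `mu_Y`
#'   (degradation ratio `gamma_r`); Y inhibits the secretion of a growth
#'   activator X (X secreted at `mu_X0` where `c_Y < 1`); growth requires
#'   `c_X > 1`.}
#' \item{`inhibitor_cascade`}{`q` growth inhibitors in a feedforward chain:
#'   chemical `i` is secreted only where chemicals `1..i-1` are all below
#'   their secretion thresholds; all inhibit growth at rescaled threshold 1.
#'   With `q = 2` and `Ks = 1` this is exactly `two_inhibitors`. Each
#'   additional inhibitor can split the existing growth zones, so the
#'   attainable number of protrusions scales like `3 * 2^(q-2)`.}
#' }
#'
#' @param name one of `"none"`, `"single_inhibitor"`, `"two_inhibitors"`,
#'   `"threshold_regulator"`, `"activator_s2"`, `"inhibitor_cascade"`.
#' @param ... scheme parameters, see Details. Common ones: `mu_X`, `mu_Y0`,
#'   `Ks`, `gamma_r`, `b`; for the cascade: `q`, `mu` (length-q rates),
#'   `gamma_r` and `Ks` (recycled to length q).
#' @return a [circuit()].
#' @examples
#' named_scheme("two_inhibitors", mu_X = 8, mu_Y0 = 65, Ks = 1, gamma_r = 1)
#' @export
named_scheme <- function(name, ...) {
  args <- list(...)
  arg <- function(key, default = NULL) {
    if (!is.null(args[[key]])) args[[key]]
    else if (!is.null(default)) default
    else stop("scheme '", name, "' requires parameter '", key, "'")
  }
  switch(match.arg(name, c("none", "single_inhibitor", "two_inhibitors",
                           "threshold_regulator", "activator_s2",
                           "inhibitor_cascade")),
    none = circuit(),
    single_inhibitor = circuit(
      chemicals = list(chemical("X", mu0 = arg("mu_X"))),
      growth_links = list(growth_link("X", Kg = 1, n = -100))),
    two_inhibitors = circuit(
      chemicals = list(
        chemical("X", mu0 = arg("mu_X")),
        chemical("Y", mu0 = arg("mu_Y0"), gamma_r = arg("gamma_r", 1),
                 secretion_links = list(secretion_link("X", Ks = arg("Ks", 1))))),
      growth_links = list(growth_link("X"), growth_link("Y"))),
    threshold_regulator = circuit(
      chemicals = list(
        chemical("X", mu0 = arg("mu_X")),
        chemical("Y", mu0 = arg("mu_Y0"), gamma_r = arg("gamma_r", 0.2),
                 secretion_links = list(secretion_link("X", Ks = arg("Ks", 0.9))),
                 secretion_max = if (arg("b", 0) == 0) NULL else
                   list(regulator = "X", b = arg("b")))),
      growth_links = list(
        growth_link("X", Kg = 1, n = -100,
                    modifiers = list(list(chemical = "Y", a = 1))))),
    activator_s2 = circuit(
      chemicals = list(
        chemical("Y", mu0 = arg("mu_Y"), gamma_r = arg("gamma_r", 0.5)),
        chemical("X", mu0 = arg("mu_X0"),
                 secretion_links = list(secretion_link("Y", Ks = 1)))),
      growth_links = list(growth_link("X", Kg = 1, n = 100))),
    inhibitor_cascade = {
      q <- arg("q")
      stopifnot(q >= 1)
      mu <- arg("mu")
      stopifnot(length(mu) == q)
      gr <- rep(arg("gamma_r", 1), length.out = q)
      Ks <- rep(arg("Ks", 1), length.out = q)
      nms <- c("X", "Y", "Z", if (q > 3) paste0("I", 4:q))[1:q]
      chems <- lapply(1:q, function(i) {
        links <- if (i > 1) lapply(1:(i - 1), function(j)
          secretion_link(nms[j], Ks = Ks[j])) else list()
        chemical(nms[i], mu0 = mu[i], gamma_r = gr[i], secretion_links = links)
      })
      circuit(chemicals = chems,
              growth_links = lapply(nms, growth_link))
    })
}
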