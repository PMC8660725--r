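## HOMA2-style indices from fasting glucose and C-peptide.
##
## The indices are defined through a steady-state model of the fasting
## glucose/insulin feedback loop, with C-peptide standing in for insulin
## secretion (C-peptide is co-secreted equimolar with insulin and cleared at
## a near-constant rate, so fasting C-peptide is proportional to secretion).
## Two dimensionless parameters describe an individual:
##   b = beta-cell function as a fraction of normal  (HOMA2-B = 100 b)
##   s = whole-body insulin sensitivity as a fraction of normal
##       (HOMA2-IR = 1 / s)
##
## Model (all concentrations relative to the healthy fasting reference
## G_ref = 4.5 mmol/l, C_ref = 0.5 nmol/l):
##   secretion:  C = b * C_ref * sigma(G) / sigma(G_ref),
##               sigma(G) = G^2 / (G^2 + K_B^2), K_B = 10 mmol/l
##               (Hill-type beta-cell dose-response, half-maximal at K_B)
##   balance:    production(C, s) = disposal(G, C, s)
##               production = (1 + kappa) / (1 + kappa * s * c),
##                 c = C / C_ref   (insulin-suppressed hepatic output,
##                 kappa = 2 sets the suppression capacity)
##               disposal  = (d0 + d1 * s * c) * phi(G) + renal(G),
##                 d0 = d1 = 0.5 (insulin-independent vs -dependent share
##                 at reference), phi(G) = G (G_ref + K_U) / (G_ref (G + K_U)),
##                 K_U = 10 mmol/l (saturable uptake in glucose),
##                 renal(G) = rho * max(0, G - G_renal) / G_ref with
##                 rho = 0.05, G_renal = 10 mmol/l (glycosuria above the
##                 renal threshold; also guarantees a steady state exists
##                 for every (b, s) since disposal is unbounded in G)
## At (b, s) = (1, 1) the steady state is exactly (G_ref, C_ref), so the
## reference healthy fasting state maps to (HOMA2-B, HOMA2-IR) = (100, 1).
## homa2() inverts the model numerically: damped Newton iteration on (b, s)
## with the forward steady state computed by root-finding on the balance
## equation.

.homa2Params <- function() {
  list(G_ref = 4.5, C_ref = 0.5, K_B = 10, K_U = 10,
       kappa = 2, d0 = 0.5, d1 = 0.5, rho = 0.05, G_renal = 10)
}

# relative beta-cell dose-response sigma(G)/sigma(G_ref)
.sigmaRel <- function(G, p = .homa2Params()) {
  (G^2 / (G^2 + p$K_B^2)) / (p$G_ref^2 / (p$G_ref^2 + p$K_B^2))
}

# relative disposal drive phi(G), phi(G_ref) = 1
.phiRel <- function(G, p = .homa2Params()) {
  G * (p$G_ref + p$K_U) / (p$G_ref * (G + p$K_U))
}

# renal glucose loss above threshold, relative units
.renalRel <- function(G, p = .homa2Params()) {
  p$rho * pmax(0, G - p$G_renal) / p$G_ref
}

# forward model: steady-state (G, C) for given b (fraction) and s (fraction)
.homa2Forward <- function(b, s, p = .homa2Params()) {
  bal <- function(G) {
    c_rel <- b * .sigmaRel(G, p)
    (1 + p$kappa) / (1 + p$kappa * s * c_rel) -
      (p$d0 + p$d1 * s * c_rel) * .phiRel(G, p) - .renalRel(G, p)
  }
  # production - disposal is strictly decreasing in G; bracket widely
  G <- stats::uniroot(bal, c(0.05, 500), tol = 1e-12)$root
  C <- b * .sigmaRel(G, p) * p$C_ref
  c(G = G, C = C)
}

#' Capping limits for HOMA2 inputs
#'
#' Fasting glucose is restricted to [3, 25] mmol/l and fasting C-peptide to
#' [0.2, 3.5] ng/ml (the operating range of the HOMA2 model); values outside
#' are replaced by the proximal limit. The C-peptide limits are defined in
#' ng/ml and converted to canonical nmol/l with [convertCPeptide()].
#'
#' @param constants Unit constants, see [unitConstants()].
#' @return Named list with \code{glucose} and \code{cpeptide} two-element
#'   vectors (nmol/l for C-peptide).
#' @export
homa2Limits <- function(constants = unitConstants()) {
  list(glucose = c(3, 25),
       cpeptide = convertCPeptide(c(0.2, 3.5), "ng_per_ml", constants))
}

#' Cap fasting glucose and C-peptide to the HOMA2 operating range
#'
#' @param glucose Fasting glucose, mmol/l (positive).
#' @param cpeptide Fasting C-peptide, nmol/l (positive).
#' @param limits See [homa2Limits()].
#'
#' @return data.frame with columns \code{glucose}, \code{cpeptide} (capped
#'   values) and logical \code{glucose_capped}, \code{cpeptide_capped}.
#'   Capping is idempotent: capping twice equals capping once.
#' @examples
#' capHomaInputs(26, 0.76)   # glucose capped to 25
#' @export
capHomaInputs <- function(glucose, cpeptide, limits = homa2Limits()) {
  if (any(!is.finite(glucose)) || any(glucose <= 0) ||
      any(!is.finite(cpeptide)) || any(cpeptide <= 0))
    stop("glucose and C-peptide must be positive and finite")
  g <- pmin(pmax(glucose, limits$glucose[1]), limits$glucose[2])
  cp <- pmin(pmax(cpeptide, limits$cpeptide[1]), limits$cpeptide[2])
  data.frame(glucose = g, cpeptide = cp,
             glucose_capped = g != glucose,
             cpeptide_capped = cp != cpeptide)
}

#' HOMA2-style beta-cell function and insulin resistance
#'
#' Computes HOMA2-B (% of normal beta-cell function) and HOMA2-IR
#' (dimensionless insulin resistance, reciprocal of fractional sensitivity)
#' from fasting glucose and fasting C-peptide by numerically inverting the
#' steady-state fasting feedback model described in the package vignette.
#' Inputs are expected pre-capped (see [capHomaInputs()]); \code{cap = TRUE}
#' applies the capping first.
#'
#' The indices are normalised so that the healthy fasting reference state
#' (4.5 mmol/l glucose, 0.5 nmol/l C-peptide) maps to (100, 1). At fixed
#' glucose both indices increase strictly with C-peptide; at fixed C-peptide
#' HOMA2-B decreases strictly with glucose.
#'
#' @param glucose Fasting glucose, mmol/l.
#' @param cpeptide Fasting C-peptide, nmol/l.
#' @param cap Apply [capHomaInputs()] before solving (default TRUE).
#' @param tol Newton convergence tolerance on the scaled residual.
#' @param maxit Maximum Newton iterations before the solver aborts with an
#'   error carrying the offending inputs.
#'
#' @return data.frame with columns \code{homa2_b} and \code{homa2_ir}, plus
#'   the capped inputs and capping flags.
#' @examples
#' homa2(4.5, 0.5)          # reference state: about (100, 1)
#' homa2(9.26, 0.76)        # hyperglycaemic, mid-range C-peptide
#' @export
homa2 <- function(glucose, cpeptide, cap = TRUE, tol = 1e-9, maxit = 50L) {
  p <- .homa2Params()
  inp <- if (cap) capHomaInputs(glucose, cpeptide) else {
    if (any(!is.finite(glucose)) || any(glucose <= 0) ||
        any(!is.finite(cpeptide)) || any(cpeptide <= 0))
      stop("glucose and C-peptide must be positive and finite")
    data.frame(glucose = glucose, cpeptide = cpeptide,
               glucose_capped = FALSE, cpeptide_capped = FALSE)
  }
  n <- nrow(inp)
  B <- IR <- numeric(n)
  for (i in seq_len(n)) {
    Gobs <- inp$glucose[i]; Cobs <- inp$cpeptide[i]
    # damped Newton on log(b), log(s): residual is the forward steady state
    # minus the observation, scaled by the observation
    th <- c(0, 0)  # log(b), log(s)
    resid <- function(th) {
      st <- .homa2Forward(exp(th[1]), exp(th[2]), p)
      c(st[["G"]] / Gobs - 1, st[["C"]] / Cobs - 1)
    }
    r <- resid(th)
    ok <- FALSE
    for (it in seq_len(maxit)) {
      if (max(abs(r)) < tol) { ok <- TRUE; break }
      h <- 1e-6
      J <- cbind((resid(th + c(h, 0)) - r) / h,
                 (resid(th + c(0, h)) - r) / h)
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        thNew <- th + lambda * step
        rNew <- tryCatch(resid(thNew), error = function(e) NULL)
        if (!is.null(rNew) && all(is.finite(rNew)) &&
            max(abs(rNew)) < max(abs(r))) break
        lambda <- lambda / 2
        if (lambda < 1e-8) { rNew <- NULL; break }
      }
      if (is.null(rNew)) break
      th <- thNew; r <- rNew
    }
    if (!ok)
      stop(sprintf(
        "HOMA2 solver failed to converge for glucose=%.4g, C-peptide=%.4g",
        Gobs, Cobs))
    B[i] <- 100 * exp(th[1])
    IR[i] <- 1 / exp(th[2])
  }
  data.frame(homa2_b = B, homa2_ir = IR,
             glucose = inp$glucose, cpeptide = inp$cpeptide,
             glucose_capped = inp$glucose_capped,
             cpeptide_capped = inp$cpeptide_capped)
}
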