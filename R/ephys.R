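#' Nernst (reversal) potential
#'
#' E = (RT/zF) ln(c_out/c_in) in mV.
#'
#' @param c_out,c_in Concentrations on the two sides (mM), > 0.
#' @param z Ion valence.
#' @param temperature Temperature (K).
#' @return Equilibrium potential in mV.
#' @examples
#' nernst(140, 140, z = -1)  # 0 mV: symmetric chloride
#' @export
nernst <- function(c_out, c_in, z = -1, temperature = 298.15) {
  if (c_out <= 0 || c_in <= 0) stop("concentrations must be positive")
  pc <- phys_constants()
  1e3 * pc$R * temperature / (z * pc$F) * log(c_out / c_in)
}

#' Conductance-voltage data from a current-voltage table
#'
#' G = I/(V - E_rev), normalised to the conductance at a designated
#' reference voltage (by convention a strongly depolarised value where
#' activation saturates; +140 and +150 mV are both in common use - see the
#' methods vignette). Points within `mask_mV` of the reversal potential
#' are masked: the driving force vanishes there and G is undefined.
#'
#' @param iv data.frame with columns `V` (mV) and `I` (pA); >= 3 voltages.
#' @param E_rev Reversal potential (mV).
#' @param ref_V Normalisation reference voltage (mV, default +140); must
#'   be present in `iv$V`.
#' @param mask_mV Half-width of the masked window around `E_rev`.
#' @return data.frame of class `"gv_data"`: `V`, `I`, `G` (nS if I in pA
#'   and V in mV), `G_norm`, `masked`.
#' @export
gv_from_iv <- function(iv, E_rev = 0, ref_V = 140, mask_mV = 2) {
  if (length(unique(iv$V)) < 3) stop("need >= 3 voltages")
  masked <- abs(iv$V - E_rev) < mask_mV
  G <- ifelse(masked, NA_real_, iv$I / (iv$V - E_rev))
  iref <- which(iv$V == ref_V)
  if (length(iref) == 0) stop("reference voltage ", ref_V, " mV not in data")
  G_ref <- G[iref[1]]
  if (!is.finite(G_ref) || G_ref == 0) stop("reference conductance is zero/undefined")
  out <- data.frame(V = iv$V, I = iv$I, G = G, G_norm = G / G_ref,
                    masked = masked)
  class(out) <- c("gv_data", "data.frame")
  out
}

#' Two-state Boltzmann fit of a G(V) curve
#'
#' Least-squares fit of G(V) = G_max / (1 + exp(-(V - V_half)/k)).
#' Start values come from the data (midpoint crossing and 10-90% rise);
#' the optimisation uses Levenberg-Marquardt least squares.
#'
#' @param gv A [gv_from_iv()] result, or any data.frame with `V` and a
#'   conductance column.
#' @param value Conductance column to fit (default `"G_norm"`).
#' @return List of class `"boltzmann_fit"`: `V_half`, `k`, `G_max`, their
#'   standard errors (`se`), and the `nls` fit object.
#' @export
boltzmann_fit <- function(gv, value = "G_norm") {
  ok <- is.finite(gv[[value]]) & (if ("masked" %in% names(gv)) !gv$masked else TRUE)
  d <- data.frame(V = gv$V[ok], G = gv[[value]][ok])
  if (nrow(d) < 4) stop("need >= 4 unmasked points spanning the rise")
  if (stats::cor(d$V, d$G) <= 0) {
    stop("conductance does not rise with voltage; degenerate data")
  }
  g_max0 <- max(d$G)
  v_half0 <- d$V[which.min(abs(d$G - g_max0 / 2))]
  k0 <- diff(range(d$V)) / 8
  fit <- minpack.lm::nlsLM(
    G ~ G_max / (1 + exp(-(V - V_half) / k)),
    data = d,
    start = list(G_max = g_max0, V_half = v_half0, k = k0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  structure(list(V_half = cf["V_half", "Estimate"],
                 k = cf["k", "Estimate"],
                 G_max = cf["G_max", "Estimate"],
                 se = c(V_half = cf["V_half", "Std. Error"],
                        k = cf["k", "Std. Error"],
                        G_max = cf["G_max", "Std. Error"]),
                 fit = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V1/2 = %.1f +/- %.1f mV, k = %.1f mV, Gmax = %.3f\n",
              x$V_half, x$se["V_half"], x$k, x$G_max))
  invisible(x)
}

#' Synthetic G(V) data for recovery tests
#'
#' Boltzmann activation curve plus iid Gaussian noise; exact at sigma = 0.
#'
#' @param V_half,k,G_max Boltzmann parameters (mV, mV, conductance units).
#' @param E_rev Reversal potential recorded in the output (mV).
#' @param sigma Noise standard deviation (conductance units), >= 0.
#' @param seed Integer seed.
#' @param V Voltage grid (mV).
#' @return data.frame of class `"gv_data"` with `V`, `G`, `G_norm`,
#'   `masked`.
#' @export
synth_gv <- function(V_half = 50, k = 25, G_max = 1, E_rev = 0,
                     sigma = 0, seed = 1,
                     V = seq(-120, 150, by = 10)) {
  stopifnot(sigma >= 0)
  g <- G_max / (1 + exp(-(V - V_half) / k))
  if (sigma > 0) {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(seed)
    g <- g + stats::rnorm(length(V), 0, sigma)
  }
  out <- data.frame(V = V, G = g, G_norm = g / G_max, masked = FALSE)
  attr(out, "E_rev") <- E_rev
  class(out) <- c("gv_data", "data.frame")
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}
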