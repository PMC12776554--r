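.e_charge_pA_ns <- 160.2176634  # elementary charge expressed in pA.ns

#' Detect complete permeation events
#'
#' Three-zone state machine per ion along the path coordinate s: below
#' (s < s_lo), inside, above (s > s_hi). An outward event is a
#' below -> inside -> above passage with no return below while inside;
#' inward is symmetric. Re-entries while inside are not double counted,
#' and a periodic-boundary jump (above -> below with no inside visit)
#' creates no event.
#'
#' @param traj A [trajectory()].
#' @param path Path object ([straight_path()] or [pathway_spline()]).
#' @param s_lo,s_hi Pore bounds on the path coordinate (A), `s_lo < s_hi`,
#'   inside the path range.
#' @param species Species to track.
#' @return data.frame (class `"event_table"`) with columns `id`, `species`,
#'   `direction` (`"outward"`/`"inward"`), `t_entry`, `t_exit` (ns), one
#'   row per completed traversal; attributes `s_lo`, `s_hi`, `total_ns`.
#' @export
detect_permeation <- function(traj, path, s_lo, s_hi, species = "ion:Cl") {
  if (!(s_lo < s_hi)) stop("s_lo must be < s_hi")
  if (s_lo < min(path$s) || s_hi > max(path$s)) {
    stop("pore bounds lie outside the path range")
  }
  p <- traj_species(traj, species)
  out <- list()
  for (ion in unique(p$id)) {
    q <- p[p$id == ion, , drop = FALSE]
    q <- q[order(q$time_ns), , drop = FALSE]
    nn <- nearest_node_cpp(q$x, q$y, q$z, path$nodes)
    s <- path$s[nn$index]
    zone <- ifelse(s < s_lo, 1L, ifelse(s > s_hi, 3L, 2L))
    r <- rle(zone)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    zz <- r$values
    if (length(zz) < 3) next
    for (k in seq_len(length(zz) - 2)) {
      if (zz[k] == 1 && zz[k + 1] == 2 && zz[k + 2] == 3) {
        out[[length(out) + 1]] <- data.frame(
          id = ion, species = species, direction = "outward",
          t_entry = q$time_ns[starts[k + 1]],
          t_exit = q$time_ns[starts[k + 2]],
          stringsAsFactors = FALSE)
      } else if (zz[k] == 3 && zz[k + 1] == 2 && zz[k + 2] == 1) {
        out[[length(out) + 1]] <- data.frame(
          id = ion, species = species, direction = "inward",
          t_entry = q$time_ns[starts[k + 1]],
          t_exit = q$time_ns[starts[k + 2]],
          stringsAsFactors = FALSE)
      }
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(id = integer(), species = character(),
               direction = character(), t_entry = numeric(),
               t_exit = numeric(), stringsAsFactors = FALSE)
  ev <- ev[order(ev$t_exit), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "s_lo") <- s_lo
  attr(ev, "s_hi") <- s_hi
  attr(ev, "total_ns") <- diff(range(traj$times))
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Block currents from an event table
#'
#' The current of each time block is I = N e / t (pA), where N is the
#' number of permeation events completed in the block (events are credited
#' to the block containing their exit time), e the elementary charge and t
#' the block length. With `signed = TRUE`, N is the net outward minus
#' inward count; otherwise the unsigned total.
#'
#' @param events An event table from [detect_permeation()].
#' @param block_ns Block length (ns), > 0.
#' @param total_ns Total trajectory time (default: from the event table).
#' @param signed Net (`TRUE`) or total (`FALSE`) event count per block.
#' @return data.frame with `block`, `t_start`, `t_end`, `n_events`,
#'   `current_pA`.
#' @export
block_currents <- function(events, block_ns, total_ns = NULL,
                           signed = FALSE) {
  stopifnot(block_ns > 0)
  if (is.null(total_ns)) total_ns <- attr(events, "total_ns")
  n_blocks <- max(1L, floor(total_ns / block_ns))
  edges <- (0:n_blocks) * block_ns
  bi <- findInterval(events$t_exit, edges, rightmost.closed = TRUE)
  bi[bi < 1] <- 1L
  bi[bi > n_blocks] <- n_blocks
  sgn <- if (signed) ifelse(events$direction == "outward", 1L, -1L) else
    rep(1L, nrow(events))
  n_ev <- vapply(seq_len(n_blocks),
                 function(b) sum(sgn[bi == b]), numeric(1))
  data.frame(block = seq_len(n_blocks),
             t_start = edges[-length(edges)], t_end = edges[-1],
             n_events = n_ev,
             current_pA = n_ev * .e_charge_pA_ns / block_ns)
}

#' Conductance from block currents
#'
#' g = mean(I)/V in pS with the spread given as the standard deviation of
#' per-block conductances.
#'
#' @param currents Numeric vector of block currents (pA) or the data.frame
#'   from [block_currents()].
#' @param voltage Membrane voltage (mV), nonzero.
#' @return List with `g_pS`, `sd_pS`, `mean_current_pA`.
#' @export
conductance <- function(currents, voltage) {
  if (voltage == 0) stop("conductance undefined at V = 0")
  if (is.data.frame(currents)) currents <- currents$current_pA
  g <- mean(currents) / voltage * 1000
  s <- if (length(currents) > 1) stats::sd(currents) / abs(voltage) * 1000 else NA_real_
  list(g_pS = g, sd_pS = s, mean_current_pA = mean(currents))
}

#' Poisson confidence interval on an event count
#'
#' Two-sided interval on the Poisson mean. The default is the Garwood
#' (exact chi-square) interval, low = qchisq(a/2, 2n)/2 (0 at n = 0),
#' high = qchisq(1-a/2, 2n+2)/2, which guarantees at least nominal
#' coverage but is conservative for discrete counts; `type = "midp"` gives
#' the mid-P variant with closer-to-nominal average coverage.
#'
#' @param n_events Nonnegative integer count.
#' @param confidence Confidence level (default 0.95).
#' @param type `"garwood"` (default) or `"midp"`.
#' @param scale Multiply both limits by this factor (e.g. e/t to convert an
#'   event-count interval to a current interval).
#' @return Numeric `c(low, high)`.
#' @export
poisson_ci <- function(n_events, confidence = 0.95,
                       type = c("garwood", "midp"), scale = 1) {
  type <- match.arg(type)
  stopifnot(n_events >= 0, n_events == round(n_events))
  a <- 1 - confidence
  if (type == "garwood") {
    low <- if (n_events == 0) 0 else stats::qchisq(a / 2, 2 * n_events) / 2
    high <- stats::qchisq(1 - a / 2, 2 * n_events + 2) / 2
  } else {
    n <- n_events
    upper_f <- function(mu) stats::ppois(n - 1, mu) + 0.5 * stats::dpois(n, mu) - a / 2
    lower_f <- function(mu) 1 - stats::ppois(n, mu) + 0.5 * stats::dpois(n, mu) - a / 2
    hi0 <- stats::qchisq(1 - a / 2, 2 * n + 2) / 2 + 1
    high <- stats::uniroot(upper_f, c(1e-12, hi0 * 2))$root
    low <- if (n == 0) 0 else stats::uniroot(lower_f, c(1e-12, hi0 * 2))$root
  }
  c(low = low, high = high) * scale
}

#' Fit a current-voltage line
#'
#' Unweighted least squares through (V, I). The slope is the conductance
#' (pS); the intercept estimates the reversal current offset.
#'
#' @param points data.frame with columns `V` (mV) and `I` (pA); at least
#'   two distinct voltages.
#' @return List of class `"iv_fit"`: `g_pS`, `g_se_pS`, `intercept_pA`,
#'   `intercept_se_pA`, `fit` (the `lm` object).
#' @export
fit_iv <- function(points) {
  if (length(unique(points$V)) < 2) stop("need >= 2 distinct voltages")
  fit <- stats::lm(I ~ V, data = points)
  cf <- suppressWarnings(summary(fit))$coefficients
  se <- function(nm) if (nm %in% rownames(cf)) cf[nm, "Std. Error"] else NA_real_
  structure(list(g_pS = unname(stats::coef(fit)["V"]) * 1000,
                 g_se_pS = se("V") * 1000,
                 intercept_pA = unname(stats::coef(fit)["(Intercept)"]),
                 intercept_se_pA = se("(Intercept)"),
                 fit = fit),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("I-V fit: g = %.3f pS (SE %.3f), intercept %.3f pA\n",
              x$g_pS, x$g_se_pS, x$intercept_pA))
  invisible(x)
}

#' Water flux through the pore centre
#'
#' Waters are binned along the path (default 3.5 A bins); a flux event is
#' counted each time a water leaves the reference bin (the bin containing
#' the path reference s = 0) into an adjacent bin between consecutive
#' frames.
#'
#' @param traj A [trajectory()].
#' @param path Path object.
#' @param bin Bin width along s (A).
#' @param radial_cutoff Only waters within this distance of the path are
#'   binned (A).
#' @param boundary_at Path coordinate of the reference bin centre
#'   (default 0).
#' @return List with `rate_per_ns`, `n_events`, `total_ns`.
#' @export
water_flux <- function(traj, path, bin = 3.5, radial_cutoff = 12,
                       boundary_at = 0) {
  p <- traj_species(traj, "water")
  total_ns <- diff(range(traj$times))
  if (total_ns <= 0) stop("trajectory spans no time")
  n_events <- 0L
  if (nrow(p) > 0) {
    edges <- seq(min(path$s), max(path$s) + bin, by = bin)
    ref_bin <- findInterval(boundary_at, edges, rightmost.closed = TRUE)
    nn <- nearest_node_cpp(p$x, p$y, p$z, path$nodes)
    s <- path$s[nn$index]
    bi <- findInterval(s, edges, rightmost.closed = TRUE)
    bi[nn$dist > radial_cutoff] <- NA_integer_
    for (w in unique(p$id)) {
      sel <- p$id == w
      b <- bi[sel][order(p$time_ns[sel])]
      prev <- b[-length(b)]
      nxt <- b[-1]
      n_events <- n_events +
        sum(!is.na(prev) & !is.na(nxt) & prev == ref_bin & nxt != ref_bin)
    }
  }
  list(rate_per_ns = n_events / total_ns, n_events = n_events,
       total_ns = total_ns)
}

#' Ion-contact statistics for a residue selection
#'
#' Fraction of frames in which at least one ion lies within `cutoff` of any
#' (heavy) atom of the selection, and the dwell times of each maximal run
#' of consecutive contact frames.
#'
#' @param traj A [trajectory()].
#' @param select_ids Particle ids forming the selection (e.g. the atoms of
#'   one residue). Hydrogens (element H) are excluded.
#' @param cutoff Contact cutoff (A), default 3.5.
#' @param species Ion species to test against.
#' @return List with `percent_time` (0-100) and `dwell_ns` (numeric vector,
#'   one entry per contact run).
#' @export
contact_stats <- function(traj, select_ids, cutoff = 3.5,
                          species = "ion:Cl") {
  if (length(select_ids) == 0) stop("empty selection")
  sel <- traj$particles[traj$particles$id %in% select_ids, , drop = FALSE]
  if (!is.null(sel$atom)) {
    heavy <- toupper(substr(gsub("[0-9]", "", sel$atom), 1, 1)) != "H"
    sel <- sel[heavy, , drop = FALSE]
  }
  if (nrow(sel) == 0) stop("selection resolves to no heavy atoms")
  ions <- traj_species(traj, species)
  times <- traj$times
  contact <- vapply(times, function(tt) {
    a <- sel[sel$time_ns == tt, , drop = FALSE]
    b <- ions[ions$time_ns == tt, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
    d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
      outer(a$z, b$z, "-")^2
    any(d2 <= cutoff^2)
  }, logical(1))
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  r <- rle(contact)
  dwell <- r$lengths[r$values] * dt
  list(percent_time = 100 * mean(contact), dwell_ns = as.numeric(dwell))
}

#' Minimum heavy-atom gate distance per frame
#'
#' @param traj A [trajectory()].
#' @param ids_a,ids_b Particle ids of the two residue selections (e.g. the
#'   two hydrophobic gate residues). Hydrogens are excluded.
#' @return data.frame with `time_ns` and `dist` (A).
#' @export
gate_metrics <- function(traj, ids_a, ids_b) {
  pick <- function(ids) {
    q <- traj$particles[traj$particles$id %in% ids, , drop = FALSE]
    if (!is.null(q$atom)) {
      heavy <- toupper(substr(gsub("[0-9]", "", q$atom), 1, 1)) != "H"
      q <- q[heavy, , drop = FALSE]
    }
    if (nrow(q) == 0) stop("selection resolves to no atoms")
    q
  }
  a <- pick(ids_a)
  b <- pick(ids_b)
  dist <- vapply(traj$times, function(tt) {
    ai <- a[a$time_ns == tt, , drop = FALSE]
    bi <- b[b$time_ns == tt, , drop = FALSE]
    d2 <- outer(ai$x, bi$x, "-")^2 + outer(ai$y, bi$y, "-")^2 +
      outer(ai$z, bi$z, "-")^2
    sqrt(min(d2))
  }, numeric(1))
  data.frame(time_ns = traj$times, dist = dist)
}

#' Helix kink angle at a residue
#'
#' The bend angle of a helix at residue i, from the least-squares axes of
#' the C-alpha runs (i-halfwindow ... i) and (i ... i+halfwindow): 180
#' degrees is straight; smaller values are more bent. The default window of
#' one helical turn (4 residues) is the smallest stable axis estimate.
#'
#' @param traj A [trajectory()].
#' @param ca_ids Ordered particle ids of consecutive C-alpha atoms along
#'   the helix.
#' @param center Index (into `ca_ids`) of the kink residue.
#' @param halfwindow Residues on each side used for the axis fits.
#' @return data.frame with `time_ns` and `angle` (degrees, in (0, 180]).
#' @export
kink_angle <- function(traj, ca_ids, center, halfwindow = 4) {
  if (center - halfwindow < 1 || center + halfwindow > length(ca_ids)) {
    stop("residue needs >= halfwindow flanking C-alpha atoms on both sides")
  }
  axis_dir <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    v <- svd(m)$v[, 1]
    ## orient along increasing residue order
    if (sum(v * (m[nrow(m), ] - m[1, ])) < 0) v <- -v
    v
  }
  ang <- vapply(traj$times, function(tt) {
    fr <- traj$particles[traj$particles$time_ns == tt, , drop = FALSE]
    coords <- fr[match(ca_ids, fr$id), c("x", "y", "z"), drop = FALSE]
    m <- as.matrix(coords)
    v1 <- axis_dir(m[(center - halfwindow):center, , drop = FALSE])
    v2 <- axis_dir(m[center:(center + halfwindow), , drop = FALSE])
    cosang <- max(-1, min(1, sum(v1 * v2)))
    180 - acos(cosang) * 180 / pi
  }, numeric(1))
  data.frame(time_ns = traj$times, angle = ang)
}
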