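#' Single orthonormal Haar analysis step
#'
#' Splits an even-length vector into its low-pass (approximation) and
#' high-pass (detail) halves using the orthonormal Haar pair:
#' `approx[k] = (x[2k-1] + x[2k]) / sqrt(2)`,
#' `detail[k] = (x[2k-1] - x[2k]) / sqrt(2)`.
#' The 1/sqrt(2) normalisation makes the step energy-preserving, so
#' Parseval's theorem holds with equality across the whole cascade.
#'
#' @param x Numeric vector of even length.
#' @return A list with numeric components `approx` and `detail`, each of
#'   length `length(x) / 2`.
#' @examples
#' haar_step(c(1, 2, 3, 4))
#' @export
haar_step <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || length(x) %% 2L != 0L) {
    stop("haar_step() requires a numeric vector of even length >= 2")
  }
  odd <- x[seq(1L, length(x), by = 2L)]
  even <- x[seq(2L, length(x), by = 2L)]
  s <- 1 / sqrt(2)
  list(approx = (odd + even) * s, detail = (odd - even) * s)
}

#' Multilevel Haar wavelet decomposition
#'
#' Applies [haar_step()] recursively to the approximation branch. For the
#' default 256-sample window and 5 levels this yields detail coefficient
#' vectors DC1..DC5 of lengths 128, 64, 32, 16, 8 and an approximation
#' vector AC5 of length 8; the total coefficient count always equals the
#' window length.
#'
#' @param x Numeric window; `length(x)` must be divisible by `2^levels`.
#' @param levels Number of decomposition levels (default 5).
#' @return An object of class `wavelet_decomposition`: a list with
#'   `details` (list of numeric vectors, level 1 first), `approx`
#'   (numeric vector), `levels`, and `wavelet = "haar"`.
#' @seealso [haar_reconstruct()], [subband_energies()]
#' @export
haar_decompose <- function(x, levels = 5L) {
  if (!is.numeric(x) || anyNA(x)) stop("window must be numeric with no NA")
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (length(x) %% (2L^levels) != 0L || length(x) < 2L^levels) {
    stop(sprintf(
      "window length %d is not divisible by 2^%d; cannot decompose",
      length(x), levels
    ))
  }
  details <- vector("list", levels)
  a <- as.numeric(x)
  for (j in seq_len(levels)) {
    step <- haar_step(a)
    details[[j]] <- step$detail
    a <- step$approx
  }
  structure(
    list(details = details, approx = a, levels = levels, wavelet = "haar"),
    class = "wavelet_decomposition"
  )
}

#' Invert a multilevel Haar decomposition
#'
#' Exact inverse of [haar_decompose()] (the transform is orthogonal, so
#' reconstruction is the adjoint of analysis).
#'
#' @param decomp A `wavelet_decomposition`.
#' @return Numeric vector of the original window length.
#' @export
haar_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  a <- decomp$approx
  s <- 1 / sqrt(2)
  for (j in rev(seq_len(decomp$levels))) {
    d <- decomp$details[[j]]
    out <- numeric(2L * length(a))
    out[seq(1L, length(out), by = 2L)] <- (a + d) * s
    out[seq(2L, length(out), by = 2L)] <- (a - d) * s
    a <- out
  }
  a
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf(
    "<wavelet_decomposition> %s, %d levels, detail lengths [%s], approx length %d\n",
    x$wavelet, x$levels,
    paste(vapply(x$details, length, 1L), collapse = ", "),
    length(x$approx)
  ))
  invisible(x)
}

#' Parseval subband energies of a wavelet decomposition
#'
#' Computes the energy held by each detail level (`E_DCj = sum(DCj^2)`),
#' the deepest approximation (`E_ACl = sum(ACl^2)`), their total, and two
#' percentage views per level: the share of total energy
#' (`100 * E_DCj / E_tot`) and the variant whose numerator also carries
#' the approximation energy (`100 * (E_ACl + E_DCj) / E_tot`). Because the
#' transform is orthonormal, `E_tot` equals the sum of squares of the raw
#' window (Parseval).
#'
#' @param decomp A `wavelet_decomposition`.
#' @return An object of class `subband_energy_profile`: list with
#'   `e_detail` (numeric, level 1 first), `e_approx`, `e_total`,
#'   `pct_detail_of_total`, `pct_with_approx`, `levels`.
#' @export
subband_energies <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  e_detail <- vapply(decomp$details, function(d) sum(d * d), numeric(1))
  e_approx <- sum(decomp$approx^2)
  e_total <- e_approx + sum(e_detail)
  if (e_total > 0) {
    pct <- 100 * e_detail / e_total
    pct_wa <- 100 * (e_approx + e_detail) / e_total
  } else {
    # all-zero window: percentages defined as 0 by convention
    pct <- rep(0, decomp$levels)
    pct_wa <- rep(0, decomp$levels)
  }
  structure(
    list(
      e_detail = e_detail, e_approx = e_approx, e_total = e_total,
      pct_detail_of_total = pct, pct_with_approx = pct_wa,
      levels = decomp$levels
    ),
    class = "subband_energy_profile"
  )
}

#' @export
print.subband_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<subband_energy_profile> E_tot = %.6g; detail %% of total: %s; approx %% = %.3f\n",
    x$e_total,
    paste(sprintf("DC%d %.3f", seq_len(x$levels), x$pct_detail_of_total),
      collapse = ", "
    ),
    if (x$e_total > 0) 100 * x$e_approx / x$e_total else 0
  ))
  invisible(x)
}

#' Freeze-indicator statistic of a window
#'
#' The scalar compared against the activation threshold. The default
#' `"dc1_fraction"` variant is the percentage of total window energy in
#' the first-level detail band (2-4 Hz at 8 Hz sampling): near-stationary
#' limbs leave almost no energy there (below 2%), walking leaves clearly
#' more (above 4%). The `"eq13_verbatim"` variant additionally carries the
#' deepest approximation energy in the numerator; with the gravity
#' baseline retained that term dominates and the variant sits near 100%
#' for every window, so it is provided for fidelity but is not the
#' default.
#'
#' @param x A `subband_energy_profile`, a `wavelet_decomposition`, or a
#'   raw numeric window (decomposed at `levels`).
#' @param variant `"dc1_fraction"` (default) or `"eq13_verbatim"`.
#' @param level Detail level used by the statistic (default 1).
#' @param levels Decomposition depth when `x` is a raw window.
#' @return The statistic in percent. Zero-energy windows return 0.
#' @examples
#' fog_statistic(c(1, 2, 3, 4), levels = 1)  # 100 * 1 / 30
#' @export
fog_statistic <- function(x, variant = c("dc1_fraction", "eq13_verbatim"),
                          level = 1L, levels = 5L) {
  variant <- match.arg(variant)
  if (is.numeric(x)) x <- haar_decompose(x, levels = levels)
  if (inherits(x, "wavelet_decomposition")) x <- subband_energies(x)
  stopifnot(inherits(x, "subband_energy_profile"))
  if (x$e_total <= 0) return(0)
  switch(variant,
    dc1_fraction = x$pct_detail_of_total[level],
    eq13_verbatim = x$pct_with_approx[level]
  )
}

#' Export wavelet coefficients as a long data frame
#'
#' Debugging helper: one row per coefficient with its band label
#' (`"DC1"`..`"DCl"`, `"ACl"`), index within the band, and value.
#'
#' @param decomp A `wavelet_decomposition`.
#' @return A data frame with columns `band`, `index`, `value`.
#' @export
coefficients_frame <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  rows <- lapply(seq_len(decomp$levels), function(j) {
    d <- decomp$details[[j]]
    data.frame(
      band = sprintf("DC%d", j), index = seq_along(d), value = d,
      stringsAsFactors = FALSE
    )
  })
  a <- decomp$approx
  rows[[length(rows) + 1L]] <- data.frame(
    band = sprintf("AC%d", decomp$levels), index = seq_along(a), value = a,
    stringsAsFactors = FALSE
  )
  do.call(rbind, rows)
}
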