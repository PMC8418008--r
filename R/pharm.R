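# Dose-response pharmacology: inhibition rate, 4PL IC50 fitting and the
# Chou-Talalay combination index.

#' CCK-8 inhibition rate
#'
#' The plate-assay formula
#' \deqn{\mathrm{inhibition} = \frac{OD_{control} - OD_{treated}}
#'   {OD_{control} - OD_{blank}} \times 100}
#' Values may exceed 100 or fall below 0 for noisy readings; set
#' `clip = TRUE` to clamp into the 0-100 range. The rate is invariant under any
#' common affine rescaling of the three ODs.
#'
#' @param odControl,odTreated,odBlank optical densities (vectors recycle).
#' @param clip clamp the result into the 0-100 range (default FALSE).
#' @return inhibition rate in percent.
#' @export
inhibitionRate <- function(odControl, odTreated, odBlank, clip = FALSE) {
  if (any(odControl <= odBlank))
    stop("odControl must exceed odBlank (no dynamic range)")
  r <- (odControl - odTreated) / (odControl - odBlank) * 100
  if (clip) r <- pmin(pmax(r, 0), 100)
  r
}

# Replicate-averaged inhibition responses from a viability table.
.viabilityResponses <- function(table) {
  stopifnot(all(c("dose", "od", "role") %in% colnames(table)))
  ctl <- mean(table$od[table$role == "control"])
  blk <- mean(table$od[table$role == "blank"])
  tr <- table[table$role == "treated", , drop = FALSE]
  if (!nrow(tr)) stop("viability table has no treated rows")
  inh <- inhibitionRate(ctl, tr$od, blk)
  agg <- tapply(inh, tr$dose, mean)
  data.frame(dose = as.numeric(names(agg)), response = as.numeric(agg))
}

.fourPL <- function(dose, bottom, top, ic50, hill)
  bottom + (top - bottom) / (1 + (ic50 / dose)^hill)

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of inhibition(\%) = bottom + (top - bottom) /
#' (1 + (IC50/dose)^hill) to replicate-averaged responses, via
#' Levenberg-Marquardt from a fixed multi-start grid of hill slopes and
#' IC50 guesses (dose quantiles), keeping the best-SSE converged fit - so
#' the result is deterministic given the data. The IC50 is the curve
#' midpoint. Degenerate inputs (all responses equal) and total
#' non-convergence return `converged = FALSE` with NA coefficients rather
#' than an error.
#'
#' @param table viability data.frame (dose/od/role/replicate) as read by
#'   [readViability()] or generated by [generateViability()].
#' @return a [DoseResponseFit-class]
#' @export
fit4PL <- function(table) {
  resp <- .viabilityResponses(table)
  if (nrow(resp) < 4L)
    stop("need at least 4 distinct positive doses to fit a 4PL")
  failed <- new("DoseResponseFit",
                coefficients = c(bottom = NA_real_, top = NA_real_,
                                 ic50 = NA_real_, hill = NA_real_),
                sse = NA_real_, converged = FALSE, data = resp)
  if (stats::sd(resp$response) < 1e-9) return(failed)
  starts <- expand.grid(
    hill = c(0.5, 1, 1.5, 2.5, 4),
    ic50 = unname(exp(stats::quantile(log(resp$dose), c(0.25, 0.5, 0.75)))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) / (1 + (ic50 / dose)^hill),
        data = resp,
        start = list(bottom = min(resp$response), top = max(resp$response),
                     ic50 = starts$ic50[i], hill = starts$hill[i]),
        lower = c(bottom = -Inf, top = -Inf, ic50 = 1e-9, hill = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(failed)
  cf <- stats::coef(best$fit)
  if (cf[["bottom"]] > cf[["top"]]) {
    # mirror-symmetric reparameterization: swap asymptotes, invert slope
    cf <- c(bottom = cf[["top"]], top = cf[["bottom"]],
            ic50 = cf[["ic50"]], hill = -cf[["hill"]])
  }
  new("DoseResponseFit",
      coefficients = c(bottom = unname(cf[["bottom"]]),
                       top = unname(cf[["top"]]),
                       ic50 = unname(cf[["ic50"]]),
                       hill = unname(cf[["hill"]])),
      sse = best$sse, converged = TRUE, data = resp)
}

#' Median-effect fit (Chou-Talalay)
#'
#' Linear least-squares fit of \eqn{\log(fa/(1-fa)) = h(\log D - \log Dm)}
#' on replicate-averaged responses; fa = inhibition / 100. Doses whose fa
#' falls outside (0, 1) carry no information for the log-odds transform and
#' are dropped with a warning.
#'
#' @param table viability data.frame.
#' @return list with Dm (uM), h (slope), r2, and the fa range used.
#' @export
medianEffectFit <- function(table) {
  resp <- .viabilityResponses(table)
  fa <- resp$response / 100
  ok <- fa > 0 & fa < 1
  if (sum(ok) < 2L)
    stop("median-effect fit needs >= 2 doses with fa in (0, 1)")
  if (any(!ok))
    warning(sum(!ok), " dose(s) with fa outside (0, 1) dropped")
  fa <- fa[ok]; d <- resp$dose[ok]
  fit <- stats::lm(log(fa / (1 - fa)) ~ log(d))
  h <- unname(stats::coef(fit)[2L])
  Dm <- exp(-unname(stats::coef(fit)[1L]) / h)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # noise-free fits are exact
  list(Dm = Dm, h = h, r2 = r2, faRange = range(fa))
}

.doseAtFa <- function(fit, fa) fit$Dm * (fa / (1 - fa))^(1 / fit$h)

#' Chou-Talalay combination index at a fixed dose ratio
#'
#' Median-effect fits for each single agent and for the fixed-ratio
#' combination (whose `dose` column is the total dose). The combination
#' total dose achieving the requested effect level fa is interpolated on
#' the combination's own median-effect fit and split into component doses
#' by `ratioA`; then
#' \deqn{CI = d_A / Dx_A + d_B / Dx_B}
#' with Dx the single-agent dose achieving fa. CI < 1 synergy, 1 Loewe
#' additivity, > 1 antagonism. Requesting an effect level outside the
#' observed fa range of any curve is an error (choose a different
#' `effectLevel`).
#'
#' @param singleA,singleB single-agent viability tables.
#' @param combo fixed-ratio combination viability table; `dose` = total
#'   dose (uM).
#' @param ratioA fraction of the combination total dose contributed by
#'   drug A (in (0, 1)).
#' @param effectLevel fraction affected fa at which CI is evaluated
#'   (default 0.5, the median effect).
#' @return a [CombinationResult-class]
#' @export
combinationIndex <- function(singleA, singleB, combo, ratioA = 0.5,
                             effectLevel = 0.5) {
  if (ratioA <= 0 || ratioA >= 1) stop("ratioA must lie in (0, 1)")
  if (effectLevel <= 0 || effectLevel >= 1)
    stop("effectLevel must lie in (0, 1)")
  fits <- list(a = medianEffectFit(singleA),
               b = medianEffectFit(singleB),
               combo = medianEffectFit(combo))
  for (nm in names(fits)) {
    rg <- fits[[nm]]$faRange
    if (effectLevel < rg[1L] - 1e-9 || effectLevel > rg[2L] + 1e-9)
      stop("effectLevel ", effectLevel, " is outside the fitted fa range ",
           sprintf("[%.3g, %.3g]", rg[1L], rg[2L]), " of curve '", nm,
           "'; choose a different effect level")
  }
  Dtot <- .doseAtFa(fits$combo, effectLevel)
  dA <- ratioA * Dtot
  dB <- (1 - ratioA) * Dtot
  ci <- dA / .doseAtFa(fits$a, effectLevel) +
        dB / .doseAtFa(fits$b, effectLevel)
  new("CombinationResult",
      fits = fits, ci = ci, effectLevel = effectLevel,
      componentDoses = c(dA = dA, dB = dB))
}
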