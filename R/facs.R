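## Flow-cytometry gating and loss-trajectory statistics. Event tables are
## plain data.frames with columns green, red (linear intensities, > 0) and
## metadata (strain, plasmid, day, bioRep, techRep). FCS binary parsing is
## out of scope: a documented CSV export convention is the contract.

.log10Floor <- function(x, floor = 1e-6) log10(pmax(x, floor))

#' Build gates from single-population control samples
#'
#' The published gating strategy for this reporter system is not specified
#' operationally, so gates are derived from pure-population controls: a
#' per-channel cut is placed at the midpoint between the two control
#' populations' mean log10 intensities. Events are then classified by
#' quadrant: plasmid-carrying = red above its cut and green below, free =
#' green above and red below, debris = below both cuts, and double-positive
#' events are left unclassified. The mean +/- `sdLimit` sd boxes of both
#' controls are recorded as construction parameters. Controls whose means
#' are closer than `minSeparation` sd in either channel are rejected as
#' non-separable.
#'
#' @param controlCarrier,controlFree event tables of pure plasmid-carrying
#'   and pure plasmid-free populations.
#' @param minSeparation minimum separation (in sd of log10 intensity)
#'   between control means, per channel (default 2).
#' @param sdLimit half-width (in sd) of the recorded control boxes.
#' @return a `GateSet` list: `greenCut`, `redCut` (log10), `boxes`,
#'   `params`.
#' @export
buildGates <- function(controlCarrier, controlFree, minSeparation = 2,
                       sdLimit = 3) {
  stopifnot(nrow(controlCarrier) > 1L, nrow(controlFree) > 1L)
  st <- function(ev) list(
    g = c(mean = mean(.log10Floor(ev$green)), sd = sd(.log10Floor(ev$green))),
    r = c(mean = mean(.log10Floor(ev$red)), sd = sd(.log10Floor(ev$red))))
  ca <- st(controlCarrier); fr <- st(controlFree)
  sepG <- abs(fr$g["mean"] - ca$g["mean"]) /
    max(fr$g["sd"], ca$g["sd"])
  sepR <- abs(fr$r["mean"] - ca$r["mean"]) /
    max(fr$r["sd"], ca$r["sd"])
  if (sepG < minSeparation || sepR < minSeparation)
    stop(sprintf("populations not separable: control means %.1f (green) and %.1f (red) sd apart",
                 sepG, sepR))
  box <- function(s) c(gLow = unname(s$g["mean"] - sdLimit * s$g["sd"]),
                       gHigh = unname(s$g["mean"] + sdLimit * s$g["sd"]),
                       rLow = unname(s$r["mean"] - sdLimit * s$r["sd"]),
                       rHigh = unname(s$r["mean"] + sdLimit * s$r["sd"]))
  structure(list(
    greenCut = unname((ca$g["mean"] + fr$g["mean"]) / 2),
    redCut = unname((ca$r["mean"] + fr$r["mean"]) / 2),
    boxes = list(carrier = box(ca), free = box(fr)),
    params = list(minSeparation = minSeparation, sdLimit = sdLimit,
                  separation = c(green = unname(sepG), red = unname(sepR)))),
    class = "GateSet")
}

#' Classify events against a GateSet
#'
#' @param events event table with `green` and `red` columns.
#' @param gates a `GateSet` from [buildGates()].
#' @return character vector per event: `"carrier"`, `"free"`, `"debris"`
#'   or `"unclassified"`.
#' @export
classifyEvents <- function(events, gates) {
  stopifnot(inherits(gates, "GateSet"))
  lg <- .log10Floor(events$green)
  lr <- .log10Floor(events$red)
  gHigh <- lg > gates$greenCut
  rHigh <- lr > gates$redCut
  ifelse(rHigh & !gHigh, "carrier",
         ifelse(gHigh & !rHigh, "free",
                ifelse(!gHigh & !rHigh, "debris", "unclassified")))
}

#' Plasmid-free fraction of a gated sample
#'
#' Fraction of plasmid-free among gated cells,
#' `nFree / (nFree + nCarrier)`; debris and unclassified events are
#' excluded. A Wilson 95% score interval is attached.
#'
#' @param events event table.
#' @param gates a `GateSet`.
#' @param level confidence level for the Wilson interval.
#' @return list with `fraction`, `nFree`, `nCarrier`, `nDebris`,
#'   `nUnclassified`, `ci` (Wilson interval).
#' @export
lossFraction <- function(events, gates, level = 0.95) {
  cls <- classifyEvents(events, gates)
  nF <- sum(cls == "free"); nC <- sum(cls == "carrier")
  if (nF + nC == 0L) stop("no events in the carrier or free gates")
  list(fraction = nF / (nF + nC), nFree = nF, nCarrier = nC,
       nDebris = sum(cls == "debris"),
       nUnclassified = sum(cls == "unclassified"),
       ci = wilsonInterval(nF, nF + nC, level))
}

#' Aggregate per-measurement fractions into a loss trajectory
#'
#' Technical replicates are averaged within each biological replicate
#' (biological replicates stay separate), then a per-day summary (mean and
#' standard error of the mean across biological replicates) is computed
#' for plotting.
#'
#' @param fractions data.frame with columns `fraction`, `strain`,
#'   `plasmid`, `day`, `bioRep`, and optionally `techRep`.
#' @return a LossTrajectory list: `replicates` (tech-averaged, one row per
#'   strain x plasmid x day x bioRep) and `summary` (per strain x plasmid
#'   x day: `mean`, `sem`, `nBioReps`).
#' @export
aggregateTrajectory <- function(fractions) {
  need <- c("fraction", "strain", "plasmid", "day", "bioRep")
  stopifnot(all(need %in% names(fractions)))
  reps <- aggregate(fraction ~ strain + plasmid + day + bioRep,
                    fractions, mean)
  summ <- do.call(rbind, by(reps, reps[c("strain", "plasmid", "day")],
    function(s) data.frame(
      strain = s$strain[1], plasmid = s$plasmid[1], day = s$day[1],
      mean = mean(s$fraction),
      sem = sd(s$fraction) / sqrt(nrow(s)),
      nBioReps = nrow(s), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  summ <- summ[order(summ$strain, summ$plasmid, summ$day), , drop = FALSE]
  list(replicates = reps[order(reps$strain, reps$plasmid, reps$day,
                               reps$bioRep), , drop = FALSE],
       summary = summ)
}

#' Compare plasmid-loss trends between two strains
#'
#' Linear model `fraction ~ day x strain` on biological-replicate-level
#' fractions (technical replicates pre-averaged), with day numeric. The
#' `day:strain` interaction coefficient is the difference in loss trend
#' between the strains; its t test is reported. Fractions are analyzed
#' untransformed by default; a logit transform is available for
#' sensitivity analysis.
#'
#' @param replicates data.frame with columns `fraction`, `day`, `strain`
#'   (two levels), e.g. the `replicates` element of
#'   [aggregateTrajectory()].
#' @param transform `"identity"` (default) or `"logit"` (with a small
#'   floor/ceiling to keep 0 and 1 finite).
#' @return list with `interaction` (estimate), `se`, `t`, `df`, `p`, and
#'   `fit`.
#' @export
compareTrends <- function(replicates, transform = c("identity", "logit")) {
  transform <- match.arg(transform)
  stopifnot(all(c("fraction", "day", "strain") %in% names(replicates)))
  strain <- factor(replicates$strain)
  if (nlevels(strain) != 2L) stop("exactly two strains are required")
  if (length(unique(replicates$day)) < 2L)
    stop("need at least 2 days per group")
  y <- replicates$fraction
  if (transform == "logit") {
    eps <- 1e-4
    y <- log(pmin(pmax(y, eps), 1 - eps) / (1 - pmin(pmax(y, eps), 1 - eps)))
  }
  dat <- data.frame(y = y, day = as.numeric(replicates$day),
                    strain = strain)
  fit <- lm(y ~ day * strain, data = dat)
  sm <- summary(fit)$coefficients
  row <- grep("^day:strain", rownames(sm))
  if (!length(row)) stop("rank-deficient design: interaction not estimable")
  list(interaction = sm[row, "Estimate"], se = sm[row, "Std. Error"],
       t = sm[row, "t value"], df = df.residual(fit),
       p = sm[row, "Pr(>|t|)"], fit = fit)
}

#' Welch's unequal-variance t test
#'
#' Two-tailed Welch t test with Satterthwaite degrees of freedom, via
#' [stats::t.test()] with `var.equal = FALSE`.
#'
#' @param x,y numeric samples, each of size `>= 2`.
#' @return list with `t`, `df`, `p`, `meanDifference`.
#' @export
welchT <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                meanDifference = 0))
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanDifference = unname(diff(rev(ht$estimate))))
}

#' Relative fitness from competition counts
#'
#' Malthusian-ratio relative fitness of the plasmid-free competitor
#' against the plasmid-carrying one over a competition interval:
#' `w = ln(NfreeFinal / NfreeInitial) / ln(NcarrierFinal / NcarrierInitial)`.
#' `w > 1` means the plasmid-free competitor outcompetes (plasmid carriage
#' is costly). Raw counts are echoed so alternative conventions can be
#' recomputed. A reference competitor that did not grow makes the
#' denominator non-positive; the result is then flagged.
#'
#' @param freeInitial,freeFinal,carrierInitial,carrierFinal event counts
#'   (e.g. events/mL), all strictly positive.
#' @return a FitnessResult list: `w`, `counts`, `flagged` (reference did
#'   not grow).
#' @export
relativeFitness <- function(freeInitial, freeFinal, carrierInitial,
                            carrierFinal) {
  counts <- c(freeInitial = freeInitial, freeFinal = freeFinal,
              carrierInitial = carrierInitial, carrierFinal = carrierFinal)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("all counts must be positive and finite")
  den <- log(carrierFinal / carrierInitial)
  flagged <- den <= 0
  if (flagged)
    warning("plasmid-carrying competitor did not grow: fitness ratio flagged")
  list(w = log(freeFinal / freeInitial) / den, counts = counts,
       flagged = flagged)
}
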