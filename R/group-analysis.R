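## Group-level modelling of plateau times and between-participant
## variability summaries.

#' Tabulate plateau (or trough) times from distance series
#'
#' Applies [detectStabilizationPoint()] to each series and collects the
#' results into the long-format table consumed by [fitPlateauLmm()].
#' With `level = "concept"` the rule is applied to every concept's own
#' distance curve; with `level = "mean"` to the concept-mean curve (one
#' row per participant and model).
#'
#' @param seriesList list of [DistanceSeries][DistanceSeries-class]
#'   (any mix of participants and feature models).
#' @param threshold residual fraction for the 5% rule.
#' @param level "concept" or "mean".
#' @return data.frame with columns participant, model, concept,
#'   plateauMs, windowKind.
#' @export
plateauTable <- function(seriesList, threshold = 0.05,
                         level = c("concept", "mean")) {
  level <- match.arg(level)
  rows <- lapply(seriesList, function(ds) {
    stopifnot(is(ds, "DistanceSeries"))
    if (level == "mean") {
      pt <- detectStabilizationPoint(conceptMeans(ds), threshold,
                                     ds@windowEndMs)
      data.frame(participant = ds@participant, model = ds@modelName,
                 concept = "(mean)", plateauMs = pt$timeMs,
                 windowKind = ds@windowKind)
    } else {
      D <- ds@distances
      plat <- vapply(seq_len(nrow(D)), function(i) {
        detectStabilizationPoint(D[i, ], threshold, ds@windowEndMs)$timeMs
      }, numeric(1))
      data.frame(participant = ds@participant, model = ds@modelName,
                 concept = rownames(D), plateauMs = plat,
                 windowKind = ds@windowKind)
    }
  })
  do.call(rbind, rows)
}

#' Linear mixed model of plateau times
#'
#' Fits `plateauMs ~ <fixed effects> + (1 | concept)` with
#' \pkg{lmerTest} (Satterthwaite degrees of freedom), returning the
#' fixed-effect F table, estimated marginal means with 95% confidence
#' intervals per feature model (via \pkg{emmeans}), and Tukey-adjusted
#' pairwise contrasts between feature models.
#'
#' @param table plateau table from [plateauTable()] (columns participant,
#'   model, concept, plateauMs).
#' @param fixed character vector of fixed effects among "model" and
#'   "participant"; with both, their interaction is included when
#'   `interaction = TRUE`.
#' @param interaction include the model x participant interaction.
#' @return list of class `plateauModelFit`: `anova` (F table),
#'   `emmeans` (data.frame model, emmean, lowerCL, upperCL),
#'   `contrasts` (Tukey-adjusted pairwise contrasts), `dfMethod`, `fit`.
#' @export
fitPlateauLmm <- function(table, fixed = "model", interaction = FALSE) {
  stopifnot(all(c("model", "concept", "plateauMs") %in% names(table)))
  fixed <- match.arg(fixed, c("model", "participant"), several.ok = TRUE)
  for (f in fixed) {
    if (length(unique(table[[f]])) < 2L)
      stop("fixed effect '", f, "' has fewer than 2 levels")
  }
  cells <- table(table$concept, table$model)
  if (any(rowSums(cells > 0) < 2L))
    stop("every concept must appear in >= 2 cells; offending concept: ",
         rownames(cells)[which(rowSums(cells > 0) < 2L)[1]])
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop("empty cell: concept '", rownames(cells)[bad[1]], "' x model '",
         colnames(cells)[bad[2]], "'")
  }
  rhs <- paste(fixed, collapse = " + ")
  if (interaction && length(fixed) == 2L) rhs <- paste(rhs, "+ model:participant")
  fml <- stats::as.formula(paste("plateauMs ~", rhs, "+ (1 | concept)"))
  dat <- table
  dat$model <- factor(dat$model)
  if ("participant" %in% names(dat)) dat$participant <- factor(dat$participant)
  dat$concept <- factor(dat$concept)
  fit <- suppressMessages(lmerTest::lmer(fml, data = dat))
  aov <- as.data.frame(stats::anova(fit, type = 3))
  aov <- data.frame(effect = rownames(aov), aov, row.names = NULL,
                    check.names = FALSE)
  emm <- emmeans::emmeans(fit, stats::as.formula("~ model"),
                          lmer.df = "satterthwaite")
  emmDf <- as.data.frame(emm)
  names(emmDf)[names(emmDf) %in% c("lower.CL", "asymp.LCL")] <- "lowerCL"
  names(emmDf)[names(emmDf) %in% c("upper.CL", "asymp.UCL")] <- "upperCL"
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  structure(list(anova = aov, emmeans = emmDf, contrasts = ctr,
                 dfMethod = "Satterthwaite", fit = fit),
            class = "plateauModelFit")
}

#' @export
print.plateauModelFit <- function(x, ...) {
  cat("Linear mixed model of plateau times (df:", x$dfMethod, ")\n\nF tests:\n")
  print(x$anova, row.names = FALSE)
  cat("\nEstimated marginal means (95% CI):\n")
  print(x$emmeans, row.names = FALSE)
  cat("\nTukey-adjusted pairwise contrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Between-participant standard deviation of the distance time course
#'
#' Per window, the sample standard deviation (n-1 denominator) across
#' participants of the concept-mean prediction-target distance.
#'
#' @param seriesList list of [DistanceSeries][DistanceSeries-class], one
#'   per participant, sharing window labels.
#' @return data.frame with columns windowEndMs and sd.
#' @export
participantSdTimecourse <- function(seriesList) {
  if (length(seriesList) < 2L) stop("need at least 2 participants")
  labs <- seriesList[[1]]@windowEndMs
  M <- t(vapply(seriesList, function(ds) {
    if (!isTRUE(all.equal(ds@windowEndMs, labs)))
      stop("participants must share window labels")
    unname(conceptMeans(ds))
  }, numeric(length(labs))))
  data.frame(windowEndMs = labs, sd = apply(M, 2, stats::sd))
}

#' Correlation of plateau times between feature models
#'
#' Pearson correlation across participants between the per-participant
#' plateau vectors of each pair of feature models.
#'
#' @param table plateau table with one row per (participant, model)
#'   (e.g. from [plateauTable()] at `level = "mean"`).
#' @return model x model correlation matrix with unit diagonal.
#' @export
plateauModelCorrelations <- function(table) {
  stopifnot(all(c("participant", "model", "plateauMs") %in% names(table)))
  wide <- stats::reshape(
    table[c("participant", "model", "plateauMs")],
    idvar = "participant", timevar = "model", direction = "wide")
  mods <- sub("^plateauMs\\.", "", names(wide)[-1])
  M <- as.matrix(wide[-1])
  colnames(M) <- mods
  if (anyNA(M)) stop("missing plateau estimate for some (participant, model)")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop("constant plateau vector (zero variance) for model: ",
         mods[which(sds == 0)[1]])
  R <- stats::cor(M)
  diag(R) <- 1
  R
}
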