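## Ablation grid over the architecture variants.

#' Named architecture variants
#'
#' Each variant is a mutation of a base [ModelConfig-class].  The
#' `tables4to8` grid enumerates the canonical ablation rows: embedding
#' on/off, standard vs depthwise-separable convolution, DAFM off /
#' 2 levels / 4 levels, CoT off, and 1/2/3 stage-2 rounds (the rows
#' `full`, `dafm_n2` and `rounds_2` coincide with the canonical model but
#' are kept as separate rows to mirror the grid).
#'
#' @param name variant name, or "tables4to8" in [runAblation()] for the
#'   whole grid.
#' @param cfg base [ModelConfig-class].
#' @return the mutated [ModelConfig-class].
#' @export
applyVariant <- function(name, cfg) {
  mut <- switch(name,
    full = cfg,
    no_embedding = { cfg@useEmbedding <- FALSE; cfg },
    sc = { cfg@convType <- "sc"; cfg },
    dsc = { cfg@convType <- "dsc"; cfg },
    no_dafm = { cfg@useDafm <- FALSE; cfg },
    dafm_n2 = { cfg@useDafm <- TRUE; cfg@nLevels <- 2L; cfg },
    dafm_n4 = { cfg@useDafm <- TRUE; cfg@nLevels <- 4L; cfg },
    no_cot = { cfg@useCot <- FALSE; cfg },
    rounds_1 = { cfg@rounds <- 1L; cfg },
    rounds_2 = { cfg@rounds <- 2L; cfg },
    rounds_3 = { cfg@rounds <- 3L; cfg },
    stop("unknown ablation variant: ", name)
  )
  validObject(mut)
  mut
}

ablationGridNames <- function(grid = "tables4to8") {
  if (identical(grid, "tables4to8")) {
    c("full", "no_embedding", "sc", "no_dafm", "dafm_n2", "dafm_n4",
      "no_cot", "rounds_1", "rounds_2", "rounds_3")
  } else {
    grid
  }
}

#' Run the ablation grid
#'
#' Trains and evaluates every requested variant under the identical split
#' and seeds, and returns a metrics table (accuracy / precision / recall /
#' F1 as percentages) with one row per variant.
#'
#' @param data a standardized [SegmentSet-class] (the whole dataset; the
#'   split is taken inside so all variants share it).
#' @param grid "tables4to8" or a character vector of variant names (see
#'   [applyVariant()]).
#' @param cfg base [ModelConfig-class].
#' @param tc a [TrainConfig-class] shared by all variants.
#' @param split optional [SplitPlan-class]; by default a subject-wise
#'   80/20 split with `tc@seed`.
#' @param verbose log progress per variant.
#' @return data.frame with columns variant, accuracy, precision, recall,
#'   f1, macroF1 (percent) and an attribute "reports" holding the
#'   [EvalReport-class] objects.
#' @export
runAblation <- function(data, grid = "tables4to8", cfg, tc = trainConfig(),
                        split = NULL, verbose = FALSE) {
  stopifnot(is(data, "SegmentSet"))
  names <- ablationGridNames(grid)
  if (is.null(split)) split <- makeSplit(data, "subject_wise", seed = tc@seed)
  trainSet <- data[trainIndices(split)]
  testSet <- data[testIndices(split)]
  stats <- fitStandardization(trainSet)
  trainSet <- standardize(trainSet, stats)
  testSet <- standardize(testSet, stats)
  desc <- sprintf("%s split, seed %d", split@mode, split@seed)
  reports <- list()
  rows <- list()
  for (nm in names) {
    vcfg <- applyVariant(nm, cfg)
    dscnetLog("info", "ablation variant %s", nm, verbose = verbose)
    fit <- trainDscnet(trainSet, vcfg, tc)
    rep <- evaluateModel(fit$store, testSet, splitDescriptor = desc,
                         seed = tc@seed)
    reports[[nm]] <- rep
    row <- reportRow(rep, nm)
    names(row)[1] <- "variant"
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Write an ablation table as CSV
#'
#' Percentages formatted with two decimals, mirroring the canonical table
#' column layout.
#'
#' @param table data.frame from [runAblation()].
#' @param path output CSV path.
#' @return (invisibly) the formatted data.frame.
#' @export
writeAblationTable <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.2f", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
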