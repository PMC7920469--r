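## Front end for taxon count tables: zero replacement and log transform,
## BMI-based phenotype grouping, end-to-end taxon selection, a synthetic
## zero-inflated count-table generator, and TSV/CSV readers.
##
## Count tables are plain numeric matrices, samples in rows (rownames =
## sample IDs) and taxa in columns (colnames = taxon names).

.checkCountTable <- function(counts) {
  .assertMatrix(counts, "counts")
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique taxon column names", call. = FALSE)
  if (is.null(rownames(counts)))
    stop("counts must have sample IDs as row names", call. = FALSE)
  invisible(counts)
}

#' Preprocess a taxon count table
#'
#' Optionally converts raw counts to per-sample relative abundances, replaces
#' zeros by 0.5 times the minimum observed positive abundance (globally by
#' default, per taxon on request), and applies the natural log transform.
#' The output is finite everywhere.
#'
#' @param counts samples x taxa nonnegative matrix with dimnames.
#' @param pseudoMode "global_min" (default): the replacement value is half
#'   the smallest positive entry of the whole table; "per_taxon_min": half
#'   the smallest positive entry of each taxon's column (an all-zero taxon
#'   is an error naming it).
#' @param relative convert rows to relative abundances first (default TRUE;
#'   set FALSE when the table already holds relative abundances or when raw
#'   counts are to be used directly).
#' @return samples x taxa numeric matrix of log abundances.
#' @examples
#' m <- matrix(c(0, 2, 8), 3, 1, dimnames = list(paste0("s", 1:3), "t1"))
#' preprocessCounts(m, relative = FALSE)  # log(1), log(2), log(8)
#' @export
preprocessCounts <- function(counts,
                             pseudoMode = c("global_min", "per_taxon_min"),
                             relative = TRUE) {
  pseudoMode <- match.arg(pseudoMode)
  .checkCountTable(counts)
  x <- counts
  if (relative) {
    tot <- rowSums(x)
    if (any(tot == 0))
      stop("sample(s) with zero total count: ",
           paste(rownames(x)[tot == 0], collapse = ", "), call. = FALSE)
    x <- x / tot
  }
  if (pseudoMode == "global_min") {
    pos <- x[x > 0]
    if (!length(pos))
      stop("table has no positive entries", call. = FALSE)
    x[x == 0] <- 0.5 * min(pos)
  } else {
    for (j in seq_len(ncol(x))) {
      col <- x[, j]
      pos <- col[col > 0]
      if (!length(pos))
        stop("taxon '", colnames(x)[j],
             "' is all zero; drop it before per-taxon zero replacement",
             call. = FALSE)
      col[col == 0] <- 0.5 * min(pos)
      x[, j] <- col
    }
  }
  log(x)
}

#' BMI group labels
#'
#' Standard cut points: underweight ("uw") below 18.5, normal ("nor")
#' 18.5 to below 25, overweight ("ow") 25 to below 30, obese ("ob") 30
#' and above (kg/m^2).
#'
#' @param bmi numeric vector of positive BMI values.
#' @return character vector of group labels.
#' @export
bmiGroup <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("bmi must be positive and finite", call. = FALSE)
  ifelse(bmi < 18.5, "uw",
         ifelse(bmi < 25, "nor",
                ifelse(bmi < 30, "ow", "ob")))
}

.validGroupings <- list(
  "all"        = c("uw", "nor", "ow", "ob"),
  "uw+ob"      = c("uw", "ob"),
  "nor+ob"     = c("nor", "ob"),
  "ow+ob"      = c("ow", "ob"),
  "uw+nor+ob"  = c("uw", "nor", "ob"),
  "uw+ow+ob"   = c("uw", "ow", "ob"),
  "nor+ow+ob"  = c("nor", "ow", "ob")
)

#' Build a binary obesity outcome from a phenotype table
#'
#' Restricts the samples to the BMI groups named by \code{grouping} and
#' returns a binary outcome that is 1 exactly for the obese group
#' (BMI >= 30).
#'
#' @param pheno data.frame with columns \code{sample_id} and \code{bmi}.
#' @param grouping one of "all", "uw+ob", "nor+ob", "ow+ob", "uw+nor+ob",
#'   "uw+ow+ob", "nor+ow+ob".
#' @return list with \code{sampleIds} (retained IDs, input order) and
#'   \code{y} (0/1 outcome of the same length).
#' @export
buildGrouping <- function(pheno, grouping = "all") {
  if (!all(c("sample_id", "bmi") %in% names(pheno)))
    stop("pheno must have columns 'sample_id' and 'bmi'", call. = FALSE)
  if (!grouping %in% names(.validGroupings))
    stop("unknown grouping '", grouping, "'; valid options: ",
         paste(names(.validGroupings), collapse = ", "), call. = FALSE)
  grp <- bmiGroup(pheno$bmi)
  keep <- grp %in% .validGroupings[[grouping]]
  y <- as.integer(grp[keep] == "ob")
  if (length(unique(y)) < 2)
    stop("grouping '", grouping, "' yields a single outcome class",
         call. = FALSE)
  list(sampleIds = as.character(pheno$sample_id[keep]), y = y)
}

#' Synthetic zero-inflated taxon count table
#'
#' Stand-in generator for real gut-microbiome data (synthetic; no external
#' data involved), emulating its two salient features: correlated taxa and
#' zero inflation. Latent log-abundances are drawn with AR(1) correlation
#' across taxa, exponentiated and rounded to counts; the smallest entries
#' are then zeroed until the target zero fraction is reached. BMI follows a
#' logistic model on the preprocessed, standardized signal taxa with the
#' given per-taxon effect, so a known support exists: obese samples get a
#' BMI at or above 30, the rest below 30.
#'
#' @param n samples. Default 200.
#' @param p taxa. Default 50.
#' @param nSignal taxa truly associated with obesity. Default 5.
#' @param zeroFraction target fraction of zero entries in (0, 1). Default 0.3.
#' @param rho AR(1) correlation of the latent log-abundances. Default 0.5.
#' @param effectSize per-taxon log-odds effect on the standardized
#'   preprocessed scale. Default 1.
#' @param seed integer seed. Default 1.
#' @return list with \code{counts} (samples x taxa integer matrix with
#'   dimnames), \code{pheno} (data.frame \code{sample_id}, \code{bmi}) and
#'   \code{support} (indices of the signal taxa).
#' @export
generateSyntheticCounts <- function(n = 200, p = 50, nSignal = 5,
                                    zeroFraction = 0.3, rho = 0.5,
                                    effectSize = 1, seed = 1L) {
  if (zeroFraction < 0 || zeroFraction >= 1)
    stop("zeroFraction must lie in [0, 1)", call. = FALSE)
  if (nSignal > p) stop("nSignal must not exceed p", call. = FALSE)
  withSeed(seed, {
    L <- .drawDesign(n, p, rho)
    counts <- matrix(pmax(1, round(exp(1.5 * L + 4))), n, p)
    ## zero-inflate: zero the smallest entries down to the target fraction,
    ## but never empty a sample row completely (every sequenced sample
    ## retains at least one read)
    targetZeros <- round(zeroFraction * n * p)
    if (targetZeros > 0) {
      ord <- order(counts, L)   # latent value breaks count ties
      rowPos <- rowSums(counts > 0)
      zeroed <- 0L
      for (idx in ord) {
        if (zeroed >= targetZeros) break
        r <- (idx - 1L) %% n + 1L
        if (rowPos[r] > 1L) {
          counts[idx] <- 0
          rowPos[r] <- rowPos[r] - 1L
          zeroed <- zeroed + 1L
        }
      }
    }
    dimnames(counts) <- list(sprintf("S%04d", seq_len(n)),
                             sprintf("taxon_%03d", seq_len(p)))
    support <- sort(sample.int(p, nSignal))
    Z <- preprocessCounts(counts, relative = TRUE)
    Zs <- scale(Z)
    Zs[is.na(Zs)] <- 0       # all-zero taxa have constant logs
    eta <- if (nSignal > 0)
      drop(Zs[, support, drop = FALSE] %*% rep(effectSize, nSignal)) - 1
    else rep(-1, n)
    ob <- stats::rbinom(n, 1, stats::plogis(eta))
    bmi <- ifelse(ob == 1,
                  30 + stats::rgamma(n, shape = 2, scale = 2.5),
                  17 + 13 * stats::rbeta(n, 2, 2))
    pheno <- data.frame(sample_id = rownames(counts), bmi = bmi,
                        stringsAsFactors = FALSE)
    list(counts = counts, pheno = pheno, support = as.integer(support))
  })
}

#' FDR-controlled taxon selection on a count table
#'
#' The full pipeline: preprocess the count table (relative abundance, zero
#' replacement, log transform), restrict to the requested BMI grouping,
#' standardize columns, estimate the covariance by shrinkage, and run the
#' aggregated knockoff filter with the logistic loss. The report lists, for
#' every taxon selected by either procedure, whether the single-run filter
#' (KO, first run's statistic at level q) and the aggregation (AKO) selected
#' it.
#'
#' @param counts samples x taxa count matrix with dimnames.
#' @param pheno data.frame with columns \code{sample_id}, \code{bmi}
#'   covering all samples in \code{counts}.
#' @param grouping BMI grouping; see [buildGrouping()]. Default "all".
#' @param q target FDR level. Default 0.1.
#' @param k number of aggregated runs. Default 5.
#' @param plus use the knockoff+ threshold. Default FALSE.
#' @param scheduleMode "geometric" (default) or "strict".
#' @param seed master seed. Default 1.
#' @param pseudoMode,relative passed to [preprocessCounts()].
#' @param ... further arguments to [aggregateKnockoffs()] (e.g.
#'   \code{nlambda}).
#' @return data.frame with columns \code{taxon}, \code{selected_by_KO},
#'   \code{selected_by_AKO}, \code{q} (one row per taxon selected by either
#'   method); the full [AggregationResult-class] is attached as attribute
#'   \code{"result"}, the retained sample count as \code{"n"}, and the
#'   analyzed taxon names as \code{"taxa"}.
#' @export
selectTaxa <- function(counts, pheno, grouping = "all", q = 0.1, k = 5L,
                       plus = FALSE,
                       scheduleMode = c("geometric", "strict"),
                       seed = 1L,
                       pseudoMode = c("global_min", "per_taxon_min"),
                       relative = TRUE, ...) {
  scheduleMode <- match.arg(scheduleMode)
  .checkCountTable(counts)
  grp <- buildGrouping(pheno, grouping)
  missing <- setdiff(grp$sampleIds, rownames(counts))
  if (length(missing))
    stop("phenotype sample(s) absent from the count table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  sub <- counts[grp$sampleIds, , drop = FALSE]
  Z <- preprocessCounts(sub, pseudoMode = pseudoMode, relative = relative)
  keep <- apply(Z, 2, stats::sd) > 0
  Z <- Z[, keep, drop = FALSE]
  if (ncol(Z) < 2)
    stop("fewer than 2 non-constant taxa after preprocessing", call. = FALSE)
  res <- aggregateKnockoffs(Z, grp$y, q = q, k = k, family = "logistic",
                            sigma = NULL, plus = plus,
                            scheduleMode = scheduleMode, seed = seed, ...)
  taxa <- colnames(Z)
  akoSel <- res@selected
  koSel <- knockoffSelect(res@statistics[[1L]]@W, q, plus)@selected
  idx <- sort(union(akoSel, koSel))
  report <- data.frame(
    taxon = taxa[idx],
    selected_by_KO = idx %in% koSel,
    selected_by_AKO = idx %in% akoSel,
    q = rep(q, length(idx)),
    stringsAsFactors = FALSE
  )
  attr(report, "result") <- res
  attr(report, "n") <- nrow(Z)
  attr(report, "taxa") <- taxa
  report
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a taxon count table from TSV/CSV
#'
#' Expects a header row of taxon names, samples in rows with the sample ID
#' in the first column.
#'
#' @param path file path (.tsv/.txt tab-separated, .csv comma-separated).
#' @return samples x taxa numeric matrix with dimnames.
#' @export
readCountTable <- function(path) {
  df <- .readTable(path)
  if (ncol(df) < 2)
    stop("count table needs a sample-ID column plus at least one taxon: ",
         path, call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric count entries in ", path, call. = FALSE)
  rownames(m) <- ids
  .checkCountTable(m)
  m
}

#' Read a phenotype table from TSV/CSV
#'
#' Expects columns \code{sample_id} and \code{bmi}.
#'
#' @param path file path.
#' @return data.frame with \code{sample_id} (character) and \code{bmi}.
#' @export
readPhenotypeTable <- function(path) {
  df <- .readTable(path)
  if (!all(c("sample_id", "bmi") %in% names(df)))
    stop("phenotype table must have columns 'sample_id' and 'bmi': ",
         path, call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$bmi <- as.numeric(df$bmi)
  df
}
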