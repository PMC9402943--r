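# Secondary analyses around the clock: correlations of iAge and
# chronological age with the stemness indices, the gene-gene correlation
# network over the selected panel, the gene-set randomization test, and the
# paired Wilcoxon differential-expression screen.

#' Correlate iAge and chronological age with the stemness indices
#'
#' For each of \{iAge, chronological age\} x \{mRNAsi, EREG-mRNAsi, mDNAsi,
#' EREG-mDNAsi\}, the correlation over pairwise-complete samples with a
#' two-sided p-value. Pearson is the default (the indices are reported
#' against linear fits); Spearman is available and is invariant to strictly
#' increasing transforms of either variable.
#'
#' @param iage [scoreCohort()] data.frame (matched to `cohort` by
#'   `sample_id`).
#' @param cohort an [InflammCohort-class] carrying stemness columns.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with `variable`, `index`, `rho`, `p_value`,
#'   `n_complete`; `rho` is missing when fewer than 3 complete pairs exist
#'   or a member is constant.
#' @export
correlateStemness <- function(iage, cohort, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  st <- stemnessData(cohort)
  if (is.null(st)) stop("cohort has no stemness indices")
  vars <- list(
    iage = iage$iage_years[match(st$sample_id, iage$sample_id)],
    chronological_age = ageYears(cohort)[match(st$sample_id, colnames(cohort))]
  )
  out <- list()
  for (v in names(vars)) {
    for (idx in c("mrnasi", "ereg_mrnasi", "mdnasi", "ereg_mdnasi")) {
      x <- vars[[v]]
      y <- st[[idx]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      rho <- p <- NA_real_
      if (n >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
        rho <- unname(ct$estimate)
        p <- ct$p.value
      }
      out[[paste(v, idx)]] <- data.frame(
        variable = v, index = idx, rho = rho, p_value = p, n_complete = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gene-gene Spearman correlation network
#'
#' All pairwise Spearman correlations among a gene subset; an edge is kept
#' when `|rho| >= threshold`, annotated with its sign. Requested genes
#' absent from the matrix are reported (message + `"missingGenes"`
#' attribute) and excluded.
#'
#' @param cohort an [InflammCohort-class] or a genes x samples matrix.
#' @param geneSubset genes to build the network over (>= 2 present).
#' @param threshold absolute-correlation edge cutoff.
#' @return data.frame with one row per unordered pair meeting the cutoff:
#'   `gene_a`, `gene_b`, `rho`, `sign` (`"positive"` / `"negative"`);
#'   attribute `threshold`.
#' @export
correlationNetwork <- function(cohort, geneSubset, threshold = 0.5) {
  expr <- if (methods::is(cohort, "InflammCohort")) exprMatrix(cohort)
          else cohort
  missing <- setdiff(geneSubset, rownames(expr))
  if (length(missing))
    message(length(missing), " gene(s) absent from matrix: ",
            paste(missing, collapse = ", "))
  genes <- intersect(geneSubset, rownames(expr))
  if (length(genes) < 2L) stop("need at least 2 genes present in the matrix")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  edges <- list()
  for (i in seq_len(length(genes) - 1L)) {
    for (j in seq(i + 1L, length(genes))) {
      rho <- spearmanRho(expr[genes[i], ], expr[genes[j], ])
      if (!is.na(rho) && abs(rho) >= threshold)
        edges[[length(edges) + 1L]] <- data.frame(
          gene_a = genes[i], gene_b = genes[j], rho = rho,
          sign = if (rho >= 0) "positive" else "negative",
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(edges)) do.call(rbind, edges)
         else data.frame(gene_a = character(), gene_b = character(),
                         rho = numeric(), sign = character(),
                         stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "missingGenes") <- missing
  out
}

#' Gene-set randomization (permutation) test
#'
#' Compares a set-level statistic of the selected genes with its null
#' distribution over `nIter` uniform draws of equally sized gene sets from
#' the pool (without replacement within each draw). The p-value uses the
#' add-one rule `p = (1 + #\{null >= observed\}) / (nIter + 1)`, so it is
#' never exactly zero. Deterministic per seed.
#'
#' @param pool character vector of candidate genes.
#' @param selected subset of `pool` whose statistic is tested.
#' @param statFn function from a character vector of genes to a scalar;
#'   see [statMeanAbsAgeCor()] and [statOverlapCount()] for the two
#'   built-in choices.
#' @param nIter number of null draws (>= 1).
#' @param seed integer seed.
#' @return list with `observed_stat`, `null_stats` (length `nIter`),
#'   `p_value`, `n_iter`, `seed`.
#' @export
randomizationTest <- function(pool, selected, statFn, nIter = 1000L,
                              seed = 1L) {
  if (nIter < 1L) stop("nIter must be >= 1")
  extra <- setdiff(selected, pool)
  if (length(extra))
    stop("selected genes not in pool: ", paste(extra, collapse = ", "))
  if (length(selected) > length(pool))
    stop("selected set larger than pool")
  withr::local_preserve_seed()
  set.seed(seed)
  observed <- statFn(selected)
  k <- length(selected)
  nullStats <- vapply(seq_len(nIter),
                      function(i) statFn(sample(pool, k)), numeric(1))
  list(
    observed_stat = observed,
    null_stats = nullStats,
    p_value = (1 + sum(nullStats >= observed)) / (nIter + 1),
    n_iter = as.integer(nIter),
    seed = as.integer(seed)
  )
}

#' @describeIn randomizationTest statistic factory: mean absolute Spearman
#'   correlation with chronological age of the genes in the set, computed
#'   on `cohort`.
#' @param cohort an [InflammCohort-class].
#' @export
statMeanAbsAgeCor <- function(cohort) {
  expr <- exprMatrix(cohort)
  age <- ageYears(cohort)
  function(genes) {
    rho <- vapply(genes, function(g) spearmanRho(expr[g, ], age), numeric(1))
    mean(abs(rho), na.rm = TRUE)
  }
}

#' @describeIn randomizationTest statistic factory: number of genes in the
#'   set that belong to `reference`.
#' @param reference character vector of reference genes.
#' @export
statOverlapCount <- function(reference) {
  function(genes) length(intersect(genes, reference))
}

#' Paired tumor-versus-normal differential-expression screen
#'
#' Per gene: `log_fc = log2((mean tumor + 1) / (mean normal + 1))` (the
#' pseudocount guards zero means), a paired Wilcoxon signed-rank p-value
#' over the within-pair differences, and Benjamini-Hochberg q-values over
#' all tested genes. A gene is significant when `|log_fc| > lfcThreshold`
#' (strict) and `q < qThreshold` (strict).
#'
#' @param tumor,normal genes x samples matrices sharing rownames.
#' @param pairing named character vector mapping tumor sample ids (names)
#'   to their matched normal sample ids (values); >= 6 pairs.
#' @param lfcThreshold absolute log2-fold-change cutoff (default 1.5).
#' @param qThreshold FDR cutoff (default 0.05).
#' @return data.frame with `gene_id`, `log_fc`, `p_value`, `fdr_q`,
#'   `significant`.
#' @export
deScreen <- function(tumor, normal, pairing, lfcThreshold = 1.5,
                     qThreshold = 0.05) {
  shared <- intersect(rownames(tumor), rownames(normal))
  if (length(shared) == 0L) stop("tumor and normal share no genes")
  badT <- setdiff(names(pairing), colnames(tumor))
  badN <- setdiff(unname(pairing), colnames(normal))
  if (length(badT) || length(badN))
    stop("unpaired samples: ", paste(c(badT, badN), collapse = ", "))
  if (length(pairing) < 6L) stop("need at least 6 tumor-normal pairs")
  tv <- tumor[shared, names(pairing), drop = FALSE]
  nv <- normal[shared, unname(pairing), drop = FALSE]
  logFc <- log2((rowMeans(tv) + 1) / (rowMeans(nv) + 1))
  p <- vapply(shared, function(g) {
    tryCatch(
      suppressWarnings(
        stats::wilcox.test(tv[g, ], nv[g, ], paired = TRUE)$p.value),
      error = function(e) 1)
  }, numeric(1))
  p[!is.finite(p)] <- 1        # all-zero differences: no evidence
  q <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene_id = shared,
    log_fc = unname(logFc),
    p_value = unname(p),
    fdr_q = unname(q),
    significant = unname(abs(logFc) > lfcThreshold & q < qThreshold),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
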