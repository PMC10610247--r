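#' Select drugs for profile analysis
#'
#' Drugs whose total report count exceeds `min_total_reports`, ranked by
#' total descending and truncated to `max_drugs`; ties at the cut are
#' broken lexicographically so the selection is reproducible.
#'
#' @param analysis an analysis-unit tibble (rows are reports).
#' @param min_total_reports strict lower bound on the per-drug total.
#' @param max_drugs cap on the number of drugs retained.
#' @return character vector of drug names, in rank order.
#' @export
select_drugs <- function(analysis, min_total_reports = 10000L,
                         max_drugs = 200L) {
  tot <- table(analysis$drug_name)
  tot <- tot[tot > min_total_reports]
  if (length(tot) < 2L) {
    stop("pipeline error: fewer than 2 drugs exceed ", min_total_reports,
         " reports", call. = FALSE)
  }
  o <- order(-as.integer(tot), names(tot))
  utils::head(names(tot)[o], max_drugs)
}

#' Tally patients per preferred term
#'
#' Number of distinct cases reporting each event PT, optionally
#' restricted to a term list (case-folded match).
#'
#' @param cohort labelled drug-event tibble.
#' @param terms optional [pruritus_terms()] tibble or character vector.
#' @return tibble with `term` and `patients`, descending.
#' @export
pt_patient_counts <- function(cohort, terms = NULL) {
  df <- unique(cohort[, c("case_id", "event_pt")])
  tal <- dplyr::count(df, .data$event_pt, name = "patients")
  names(tal)[1L] <- "term"
  if (!is.null(terms)) {
    term_set <- if (is.data.frame(terms)) terms$term else terms
    tal <- tal[tolower(tal$term) %in% tolower(term_set), ]
  }
  tal[order(-tal$patients, tal$term), ]
}

#' Select preferred terms for the profile matrix
#'
#' Terms with at least `min_patients` reported patients, in descending
#' patient-count order.
#'
#' @param term_counts tibble with `term` and `patients` columns (e.g.
#'   [pt_patient_counts()] or the packaged [pruritus_terms()] tally).
#' @param min_patients minimum reported patient count.
#' @return character vector of terms.
#' @export
select_pts <- function(term_counts, min_patients = 50L) {
  keep <- term_counts[term_counts$patients >= min_patients, ]
  if (nrow(keep) < 2L) {
    stop("pipeline error: fewer than 2 terms have >= ", min_patients,
         " patients", call. = FALSE)
  }
  keep$term[order(-keep$patients, keep$term)]
}

#' Drug-by-term lnROR profile matrix
#'
#' For every selected (drug, PT) pair, the 2x2 table contrasts that drug
#' against all other drugs and that PT against all other events over the
#' full drug-event analysis set; the Haldane-Anscombe-corrected lnROR
#' fills the cell. The correction guarantees every cell is finite, so the
#' matrix has no missing values.
#'
#' @param analysis a `"drug_event"` analysis tibble from
#'   [make_analysis_set()].
#' @param drugs character vector of row drugs (see [select_drugs()]).
#' @param pts character vector of column PTs (see [select_pts()]).
#' @return object of class `ror_matrix`: list with `values` (numeric
#'   drugs x PTs lnROR matrix), `drug_totals` and `pt_patients`.
#' @export
build_ror_matrix <- function(analysis, drugs, pts) {
  ct <- table(factor(analysis$drug_name), factor(analysis$event_pt))
  row_tot <- rowSums(ct)
  col_tot <- colSums(ct)
  total <- sum(ct)
  miss_d <- setdiff(drugs, rownames(ct))
  miss_p <- setdiff(pts, colnames(ct))
  if (length(miss_d) || length(miss_p)) {
    stop("selection not present in analysis set: ",
         paste(c(miss_d, miss_p), collapse = ", "), call. = FALSE)
  }
  a <- ct[drugs, pts, drop = FALSE]
  b <- row_tot[drugs] - a
  cc <- matrix(col_tot[pts], length(drugs), length(pts), byrow = TRUE) - a
  d <- total - a - b - cc
  ln <- matrix(compute_ror(as.vector(a), as.vector(b), as.vector(cc),
                           as.vector(d))$ln_ror,
               length(drugs), length(pts), dimnames = list(drugs, pts))
  pat <- pt_patient_counts(analysis)
  structure(
    list(values = ln,
         drug_totals = row_tot[drugs],
         pt_patients = stats::setNames(pat$patients, pat$term)[pts]),
    class = "ror_matrix")
}

#' Principal component analysis on the covariance matrix
#'
#' Column-mean centering with no scaling (covariance PCA, not
#' correlation): the PT columns keep their natural lnROR variances.
#' Components are ordered by decreasing eigenvalue; the contribution
#' ratio of a component is its eigenvalue divided by the total variance.
#' Sign convention: each loading vector's largest-magnitude element is
#' made positive (and its scores flipped accordingly) so results are
#' reproducible across linear-algebra backends.
#'
#' @param x a numeric matrix (rows = drugs, columns = PTs) or a
#'   [build_ror_matrix()] result.
#' @return list of class `pca_result`: `contributions` (variance
#'   fractions, all components), `loadings` (PT x component), `scores`
#'   (drug x component), `eigenvalues`, `center`, `n_components`.
#' @export
pca_covariance <- function(x) {
  m <- if (inherits(x, "ror_matrix")) x$values else as.matrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("matrix must be finite", call. = FALSE)
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  eig <- pr$sdev^2
  if (sum(eig) <= .Machine$double.eps) {
    stop("degenerate input: matrix has no variance", call. = FALSE)
  }
  loadings <- pr$rotation
  scores <- pr$x
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(contributions = eig / sum(eig), loadings = loadings,
         scores = scores, eigenvalues = eig, center = pr$center,
         n_components = ncol(loadings)),
    class = "pca_result")
}

#' Ward hierarchical clustering of drug scores
#'
#' Agglomerative Ward clustering on Euclidean distance over the first
#' `n_components` principal-component score columns (Ward's minimum
#' within-cluster-variance criterion; merge heights are non-decreasing),
#' cut into `k` clusters. Deterministic under fixed input.
#'
#' @param pca a [pca_covariance()] result.
#' @param n_components number of leading score columns to cluster on.
#' @param k number of clusters to cut.
#' @return list of class `cluster_result`: `labels` (named drug ->
#'   cluster id), `merge`, `height`, `order`, `k`, `n_components` and the
#'   underlying `hclust` object.
#' @export
ward_cluster <- function(pca, n_components = 3L, k = 6L) {
  s <- pca$scores[, seq_len(min(n_components, ncol(pca$scores))), drop = FALSE]
  if (k > nrow(s)) {
    stop("k = ", k, " exceeds the number of drugs (", nrow(s), ")",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(s), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  structure(
    list(labels = labels, merge = hc$merge, height = hc$height,
         order = hc$order, k = as.integer(k),
         n_components = ncol(s), hclust = hc),
    class = "cluster_result")
}

#' Per-cluster principal-component signatures
#'
#' For each cluster and component: the mean drug score and its sign,
#' supporting the "positively/negatively correlated with PC k" reading of
#' a cluster.
#'
#' @param cluster a [ward_cluster()] result.
#' @param pca the [pca_covariance()] result it was built from.
#' @param n_components how many components to summarise.
#' @return tibble with `cluster`, `component`, `mean_score`, `sign`.
#' @export
cluster_signatures <- function(cluster, pca,
                               n_components = cluster$n_components) {
  s <- pca$scores[, seq_len(n_components), drop = FALSE]
  out <- lapply(sort(unique(cluster$labels)), function(cl) {
    m <- colMeans(s[cluster$labels == cl, , drop = FALSE])
    tibble::tibble(cluster = cl, component = seq_along(m),
                   mean_score = unname(m), sign = sign(unname(m)))
  })
  dplyr::bind_rows(out)
}

#' Rand index between two partitions
#'
#' Fraction of point pairs on which two clusterings agree (together in
#' both or separated in both); 1 means identical partitions.
#'
#' @param a,b cluster label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
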