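# Mechanism-of-action retrieval: split drugs into reference and query
# sets, rank references by set-level distance (Wasserstein over embedding
# sets, or mean squared Euclidean distance over expression vectors), and
# score top-k intersect accuracy, mean average precision and folds of
# enrichment.

#' Construct a perturbation record for retrieval
#'
#' @param perturbation_id character id.
#' @param moa_labels non-empty character vector of MOA labels.
#' @param embedding_set optional matrix of per-image embeddings.
#' @param expression optional expression vector.
#' @param target_label optional target gene label.
#' @return object of class `perturbation_record`.
#' @export
perturbation_record <- function(perturbation_id, moa_labels,
                                embedding_set = NULL, expression = NULL,
                                target_label = "") {
  pd_assert(length(moa_labels) >= 1L, "moa_labels must be non-empty")
  structure(list(perturbation_id = as.character(perturbation_id),
                 moa_labels = unique(as.character(moa_labels)),
                 embedding_set = embedding_set,
                 expression = expression,
                 target_label = target_label),
            class = "perturbation_record")
}

#' Split records into reference and query sets
#'
#' Random split at `reference_fraction` (default 47/69, the classic
#' reference/query ratio for a 69-drug panel). Queries whose MOA set has
#' no intersection with the union of reference MOAs are dropped, so every
#' retained query is answerable.
#'
#' @param records list of [perturbation_record] (>= 3).
#' @param reference_fraction fraction of records used as reference.
#' @param seed integer seed.
#' @return list with `reference` and `query` record lists.
#' @export
split_reference_query <- function(records, reference_fraction = 47 / 69, seed = 1) {
  pd_assert(length(records) >= 3L, "need at least 3 records")
  n_ref <- round(reference_fraction * length(records))
  pd_assert(n_ref >= 1L && n_ref < length(records), "split leaves an empty side")
  idx <- with_seed(derive_seed(seed, "refquery"),
                   sample(seq_along(records), n_ref))
  reference <- records[sort(idx)]
  query <- records[setdiff(seq_along(records), idx)]
  ref_moas <- unique(unlist(lapply(reference, function(r) r$moa_labels)))
  query <- Filter(function(r) length(intersect(r$moa_labels, ref_moas)) > 0, query)
  pd_assert(length(query) >= 1L, "no query has an MOA present in the reference set")
  list(reference = reference, query = query)
}

#' Rank references by distance to one query
#'
#' Wasserstein distance between embedding sets (`distance = "wasserstein"`)
#' or mean squared Euclidean distance between expression vectors
#' (`distance = "mse"`). Ascending stable sort; exact ties broken by
#' lexicographic reference id.
#'
#' @param query a [perturbation_record].
#' @param references list of [perturbation_record] with the same modality.
#' @param distance `"wasserstein"` or `"mse"`.
#' @return object of class `retrieval_result`: query id, ranked reference
#'   ids, distances, and the relevance flag per rank (MOA intersection).
#' @export
rank_references <- function(query, references, distance = c("wasserstein", "mse")) {
  distance <- match.arg(distance)
  dists <- vapply(references, function(ref) {
    if (distance == "wasserstein") {
      pd_assert(!is.null(query$embedding_set) && !is.null(ref$embedding_set),
                "wasserstein distance requires embedding sets on both records")
      wasserstein_set(query$embedding_set, ref$embedding_set, p = 1)
    } else {
      pd_assert(!is.null(query$expression) && !is.null(ref$expression),
                "mse distance requires expression vectors on both records")
      mean((query$expression - ref$expression)^2)
    }
  }, 0)
  ids <- vapply(references, function(r) r$perturbation_id, "")
  ord <- order(dists, ids)
  relevant <- vapply(references[ord], function(r) {
    length(intersect(r$moa_labels, query$moa_labels)) > 0
  }, TRUE)
  structure(list(query_id = query$perturbation_id,
                 reference_ids = ids[ord],
                 distances = dists[ord],
                 relevant = relevant,
                 query_moas = query$moa_labels),
            class = "retrieval_result")
}

#' Top-k retrieval accuracy
#'
#' A query counts as correct if the union of MOA labels of its k nearest
#' references intersects the query's MOA set.
#'
#' @param results list of [rank_references] outputs.
#' @param k neighbourhood size; must not exceed the reference count.
#' @return proportion of correct queries.
#' @export
topk_accuracy <- function(results, k) {
  pd_assert(all(vapply(results, function(r) length(r$reference_ids) >= k, TRUE)),
            "k exceeds the reference count")
  mean(vapply(results, function(r) any(r$relevant[seq_len(k)]), TRUE))
}

#' Average precision of a ranked relevance list
#'
#' `AP = sum_k (R_k - R_{k-1}) P_k` with precision `P_k` and recall `R_k`
#' computed at every rank; equals the mean of precision at the ranks of
#' the relevant items.
#'
#' @param ranked_relevance_flags logical vector, best rank first, with at
#'   least one `TRUE`.
#' @return scalar AP in `(0, 1]`.
#' @export
average_precision <- function(ranked_relevance_flags) {
  fl <- as.logical(ranked_relevance_flags)
  pd_assert(any(fl), "no relevant items in the ranking")
  n_rel <- sum(fl)
  tp <- cumsum(fl)
  precision <- tp / seq_along(fl)
  recall <- tp / n_rel
  sum((recall - c(0, recall[-length(recall)])) * precision)
}

#' Mean average precision over queries
#'
#' Queries without any relevant item are skipped with a warning.
#'
#' @param queries list of logical ranked-relevance vectors (or of
#'   `retrieval_result` objects, whose `$relevant` field is used).
#' @return scalar mAP.
#' @export
mean_average_precision <- function(queries) {
  flags <- lapply(queries, function(q) {
    if (inherits(q, "retrieval_result")) q$relevant else as.logical(q)
  })
  usable <- vapply(flags, any, TRUE)
  if (!all(usable)) warning(sum(!usable), " query(ies) without relevant items skipped")
  pd_assert(any(usable), "no query has a relevant item")
  mean(vapply(flags[usable], average_precision, 0))
}

#' Folds of enrichment of a ranked relevance list
#'
#' Odds ratio of the 2 x 2 table crossing (above vs below a rank
#' threshold) with (same-treatment vs different-treatment). The threshold
#' is a quantile of the ranked list (default 0.90: the top 10% of ranks
#' count as "above"). The Haldane-Anscombe +0.5 correction is applied when
#' any cell is zero.
#'
#' @param ranked_relevance_flags logical vector, best rank first
#'   (length >= 10, both classes present).
#' @param threshold_quantile rank quantile defining "top" (default 0.90).
#' @return odds ratio (scalar > 0).
#' @export
folds_of_enrichment <- function(ranked_relevance_flags, threshold_quantile = 0.90) {
  fl <- as.logical(ranked_relevance_flags)
  pd_assert(length(fl) >= 10L, "need a ranking of length >= 10")
  pd_assert(any(fl) && any(!fl), "both relevance classes must be present")
  n_top <- as.integer(ceiling((1 - threshold_quantile) * length(fl)))
  n_top <- max(1L, min(n_top, length(fl) - 1L))
  top <- fl[seq_len(n_top)]; rest <- fl[-seq_len(n_top)]
  a <- sum(top); b <- sum(!top)       # above threshold: same / different
  c_ <- sum(rest); d <- sum(!rest)    # below threshold: same / different
  if (min(a, b, c_, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a / b) / (c_ / d)
}
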