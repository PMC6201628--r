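# Hypergeometric significance of herb-disease co-occurrence in the
# literature. Retrieval is out of scope: the statistic consumes counts.

#' Default literature corpus size
#'
#' Total number of PubMed records used as the sampling universe for the
#' co-occurrence test.
#' @export
DEFAULT_CORPUS_SIZE <- 22188039L

#' Hypergeometric p-value for herb-disease literature co-occurrence
#'
#' Given a corpus of `N` articles of which `K` mention the disease, and `n`
#' articles mentioning the herb, tests whether observing `k` articles
#' mentioning both is more than chance:
#' `P = 1 - sum_{i=0}^{k-1} C(K, i) C(N-K, n-i) / C(N, n)`,
#' i.e. the upper tail `P(X >= k)` of the hypergeometric distribution.
#' Computed via [stats::phyper()], which works in log-space internally, so
#' corpus sizes in the tens of millions are safe.
#'
#' @param k Number of articles mentioning both herb and disease.
#' @param K Number of disease articles.
#' @param n Number of herb articles.
#' @param N Corpus size (default [DEFAULT_CORPUS_SIZE]).
#' @return Numeric p-value in `[0, 1]`; `k = 0` gives exactly 1.
#' @examples
#' cooccurrence_pvalue(k = 2, K = 4, n = 3, N = 10)  # 1/3
#' @export
cooccurrence_pvalue <- function(k, K, n, N = DEFAULT_CORPUS_SIZE) {
  if (any(c(k, K, n, N) < 0)) stop("counts must be non-negative")
  if (K > N || n > N) stop("K and n cannot exceed the corpus size N")
  if (k > min(K, n)) {
    stop("k = ", k, " exceeds min(K, n) = ", min(K, n))
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Co-occurrence p-values for a table of herb-disease counts
#'
#' @param counts Data frame with columns `herb_id`, `disease_id`, `K`, `n`,
#'   `k`.
#' @param corpus_size Corpus size `N` shared by all rows.
#' @param alpha Significance threshold (default 0.05).
#' @return The input with `pvalue` and `significant` columns appended.
#' @export
cooccurrence_table <- function(counts, corpus_size = DEFAULT_CORPUS_SIZE,
                               alpha = 0.05) {
  need <- c("herb_id", "disease_id", "K", "n", "k")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  counts$pvalue <- mapply(cooccurrence_pvalue, counts$k, counts$K, counts$n,
                          MoreArgs = list(N = corpus_size))
  counts$significant <- counts$pvalue < alpha
  counts
}
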