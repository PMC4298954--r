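#' Trichotomize per-gene expression change after hypomethylating treatment
#'
#' A gene is "up" when post - pre >= log2(fold_threshold), "down" when
#' pre - post >= log2(fold_threshold) (boundaries inclusive), else
#' "constant". Genes missing in either condition are excluded with a
#' message.
#'
#' @param pre,post named numeric vectors of log2 expression per gene.
#' @param fold_threshold linear fold-change threshold (> 1, default 2).
#' @return named factor with levels up / down / constant over the common
#'   genes.
#' @export
trichotomize <- function(pre, post, fold_threshold = 2) {
  stopifnot(fold_threshold > 1)
  common <- intersect(names(pre), names(post))
  dropped <- length(union(names(pre), names(post))) - length(common)
  if (dropped > 0)
    message(sprintf("trichotomize: %d gene(s) missing in one condition excluded",
                    dropped))
  d <- post[common] - pre[common]
  thr <- log2(fold_threshold)
  cat_chr <- ifelse(d >= thr, "up", ifelse(-d >= thr, "down", "constant"))
  factor(stats::setNames(cat_chr, common),
         levels = c("up", "down", "constant"))
}

#' Standard priors for the induced-vs-suppressed posterior
#'
#' `uninformative` is the flat Dirichlet(1, 1, 1); `conservative` is
#' Dirichlet(1, 1, 8), placing most prior mass on the "constant" category to
#' encode that most genes do not change expression after treatment.
#'
#' @return named list of length-3 numeric vectors (up, down, constant).
#' @export
default_aza_priors <- function() {
  list(uninformative = c(up = 1, down = 1, constant = 1),
       conservative = c(up = 1, down = 1, constant = 8))
}

#' Posterior probability that more genes are induced than suppressed
#'
#' Model: (n_up, n_down, n_const) ~ Multinomial(p_up, p_down, p_const) with
#' a Dirichlet prior. By the aggregation property of the Dirichlet, after
#' marginalizing p_const the ratio p_up / (p_up + p_down) is
#' Beta(a_up + n_up, a_down + n_down), so
#' P(p_up > p_down | counts) = P(Beta > 1/2), evaluated in closed form.
#'
#' @param n_up,n_down,n_const non-negative integer counts.
#' @param prior length-3 positive numeric (up, down, constant);
#'   default flat.
#' @param prior_name label stored in the result.
#' @return a `PosteriorResult` list: `posterior_up_gt_down`, `prior_name`,
#'   `prior_parameters`, `counts`.
#' @export
posterior_up_exceeds_down <- function(n_up, n_down, n_const,
                                      prior = c(1, 1, 1),
                                      prior_name = "uninformative") {
  stopifnot(n_up >= 0, n_down >= 0, n_const >= 0)
  if (any(prior <= 0)) stop("prior parameters must be positive")
  a1 <- prior[1] + n_up
  a2 <- prior[2] + n_down
  p <- stats::pbeta(0.5, a1, a2, lower.tail = FALSE)
  structure(list(posterior_up_gt_down = p,
                 prior_name = prior_name,
                 prior_parameters = prior,
                 counts = c(up = n_up, down = n_down, constant = n_const)),
            class = "PosteriorResult")
}

#' Posterior grid over cell lines, gene categories and priors
#'
#' For every (cell line, category, prior) cell: trichotomizes the paired
#' pre/post expression restricted to the category's genes and computes the
#' posterior probability that more genes are induced than suppressed.
#' `pooled = TRUE` adds per-category rows that sum counts across all cell
#' lines (the pooled-by-type view).
#'
#' @param aza an `AzaPanel`: list with `pre` and `post` gene x cell-line
#'   log2 matrices sharing dimnames, and optionally `cell_type` (named
#'   "E"/"M" per cell line).
#' @param categories named list of gene symbol vectors.
#' @param priors named list of length-3 positive numeric vectors; default
#'   [default_aza_priors()].
#' @param fold_threshold linear fold-change threshold (default 2).
#' @param pooled also report counts pooled across cell lines.
#' @return data.frame: `cell_line` ("pooled" for pooled rows), `cell_type`,
#'   `category`, `prior`, `n_up`, `n_down`, `n_const`, `posterior`.
#' @export
aza_report <- function(aza, categories, priors = default_aza_priors(),
                       fold_threshold = 2, pooled = TRUE) {
  stopifnot(identical(dimnames(aza$pre), dimnames(aza$post)))
  cells <- colnames(aza$pre)
  genes <- rownames(aza$pre)
  cell_type <- aza$cell_type %||% stats::setNames(rep(NA_character_,
                                                      length(cells)), cells)
  rows <- list()
  pooled_counts <- list()
  for (cat_nm in names(categories)) {
    members <- intersect(categories[[cat_nm]], genes)
    if (length(members) == 0) {
      warning(sprintf("category '%s' has no measured gene; skipped", cat_nm))
      next
    }
    for (cl in cells) {
      tri <- trichotomize(stats::setNames(aza$pre[members, cl], members),
                          stats::setNames(aza$post[members, cl], members),
                          fold_threshold)
      cnt <- table(tri)
      # pooled view aggregates counts within cell type (falls back to one
      # pool when types are unknown)
      ct <- cell_type[[cl]]
      key <- paste(cat_nm, if (is.null(ct) || is.na(ct)) "all" else ct,
                   sep = "\r")
      pooled_counts[[key]] <- (pooled_counts[[key]] %||% c(up = 0, down = 0,
                                                           constant = 0)) +
        c(up = cnt[["up"]], down = cnt[["down"]], constant = cnt[["constant"]])
      for (pr_nm in names(priors)) {
        post <- posterior_up_exceeds_down(cnt[["up"]], cnt[["down"]],
                                          cnt[["constant"]],
                                          priors[[pr_nm]], pr_nm)
        rows[[length(rows) + 1]] <- data.frame(
          cell_line = cl, cell_type = cell_type[[cl]], category = cat_nm,
          prior = pr_nm, n_up = cnt[["up"]], n_down = cnt[["down"]],
          n_const = cnt[["constant"]],
          posterior = post$posterior_up_gt_down, stringsAsFactors = FALSE)
      }
    }
  }
  if (pooled) {
    for (key in names(pooled_counts)) {
      cnt <- pooled_counts[[key]]
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      for (pr_nm in names(priors)) {
        post <- posterior_up_exceeds_down(cnt[["up"]], cnt[["down"]],
                                          cnt[["constant"]],
                                          priors[[pr_nm]], pr_nm)
        rows[[length(rows) + 1]] <- data.frame(
          cell_line = "pooled", cell_type = parts[2], category = parts[1],
          prior = pr_nm, n_up = cnt[["up"]], n_down = cnt[["down"]],
          n_const = cnt[["constant"]],
          posterior = post$posterior_up_gt_down, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
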