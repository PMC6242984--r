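# Categorization performance: confusion matrices, hits, hit reaction times
# and modal confusions.

validate_responses <- function(responses) {
  need <- c("stimulus_id", "expression", "response")
  if (!all(need %in% names(responses))) {
    stop("responses need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  labs <- expression_labels()
  bad <- which(!responses$response %in% labs | !responses$expression %in% labs)
  if (length(bad)) {
    stop("unknown expression label in response row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(responses)
}

row_prop <- function(d) {
  labs <- expression_labels()
  counts <- vapply(labs, function(r) sum(d$response == r), numeric(1))
  counts / sum(counts)
}

#' Stimulus-by-response confusion matrix
#'
#' Rows are stimulus expressions, columns response expressions, in the
#' canonical label order; each row sums to 1 and the diagonal holds the hit
#' proportions. `by = "items"` (default) computes per-stimulus response
#' proportions first and averages them within expression, treating stimuli
#' as the units of analysis; `by = "pooled"` normalizes raw trial counts.
#'
#' @param responses data.frame with `stimulus_id`, `expression`, `response`.
#' @param by `"items"` or `"pooled"`.
#' @return List of class `confusion_matrix` with `prop` (6 x 6), `n`
#'   (trials per stimulus row) and `by`.
#' @export
confusion_matrix <- function(responses, by = c("items", "pooled")) {
  by <- match.arg(by)
  validate_responses(responses)
  labs <- expression_labels()
  m <- matrix(0, 6, 6, dimnames = list(stimulus = labs, response = labs))
  n <- stats::setNames(numeric(6), labs)
  for (e in labs) {
    d <- responses[responses$expression == e, , drop = FALSE]
    n[e] <- nrow(d)
    if (!nrow(d)) next
    if (by == "pooled") {
      m[e, ] <- row_prop(d)
    } else {
      per_item <- t(vapply(split(d, d$stimulus_id), row_prop, numeric(6)))
      m[e, ] <- colMeans(per_item)
    }
  }
  structure(list(prop = m, n = n, by = by), class = "confusion_matrix")
}

#' Hit proportions and correct-response reaction times
#'
#' Hits are the diagonal of the confusion matrix computed from the same
#' trials; RT statistics use correct trials only (per-stimulus means under
#' `by = "items"`, then averaged across the expression's stimuli). An
#' expression with no correct trial gets `NA` RTs.
#'
#' @param responses data.frame with `stimulus_id`, `expression`, `response`
#'   and `rt_ms`.
#' @param by `"items"` or `"pooled"`.
#' @return data.frame per expression: `hit_prop`, `rt_mean_ms`, `rt_sd_ms`.
#' @export
hits_and_rts <- function(responses, by = c("items", "pooled")) {
  by <- match.arg(by)
  validate_responses(responses)
  cm <- confusion_matrix(responses, by)
  labs <- expression_labels()
  out <- data.frame(expression = labs, hit_prop = diag(cm$prop),
                    rt_mean_ms = NA_real_, rt_sd_ms = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  for (i in seq_along(labs)) {
    d <- responses[responses$expression == labs[i] &
                     responses$response == labs[i], , drop = FALSE]
    if (!nrow(d) || !"rt_ms" %in% names(d)) next
    if (by == "pooled") {
      out$rt_mean_ms[i] <- mean(d$rt_ms)
      out$rt_sd_ms[i] <- sd0(d$rt_ms)
    } else {
      per_item <- vapply(split(d$rt_ms, d$stimulus_id), mean, numeric(1))
      out$rt_mean_ms[i] <- mean(per_item)
      out$rt_sd_ms[i] <- sd0(per_item)
    }
  }
  out
}

#' Modal confusion of an expression
#'
#' The largest off-diagonal entry of the expression's confusion-matrix row;
#' ties are reported as multiple labels.
#'
#' @param cm A `confusion_matrix` (or bare 6 x 6 row-stochastic matrix with
#'   dimnames).
#' @param expression Stimulus expression.
#' @return List with `response` (character, >= 1 labels) and `proportion`.
#' @export
modal_confusion <- function(cm, expression) {
  m <- if (inherits(cm, "confusion_matrix")) cm$prop else cm
  if (!expression %in% rownames(m)) {
    stop("expression '", expression, "' not in confusion matrix",
         call. = FALSE)
  }
  row <- m[expression, ]
  off <- row[setdiff(names(row), expression)]
  top <- max(off)
  if (top <= 0) {
    return(list(response = character(0), proportion = 0))
  }
  list(response = names(off)[off >= top - 1e-12], proportion = unname(top))
}
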