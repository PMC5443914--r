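# Synthetic questionnaire respondents. The model is deliberately
# simple and controllable: item-independent Bernoulli correctness for
# the multiple-choice knowledge test (with a pre->post uplift), and a
# truncated, discretised Gaussian for Likert / semantic-differential
# items. These are fixtures for exercising the scoring and statistics
# pipeline, not claims about human response behaviour.

#' Define a synthetic respondent model for the knowledge test
#'
#' Defaults mirror the stated study world: a group-level pre-test
#' proportion correct of 0.54 with a post-test uplift of 0.17 on the
#' probability scale.
#'
#' @param n number of respondents.
#' @param p_correct per-item probability of a correct pre-test answer
#'   (recycled to the number of items).
#' @param uplift post-test shift per item: added on the probability
#'   scale (clamped to `[0, 1]`) or, with
#'   `uplift_scale = "logodds"`, added to the item's log-odds.
#' @param uplift_scale `"probability"` (default) or `"logodds"`.
#' @param seed generator seed.
#' @return object of class `respondent_model`.
#' @export
respondent_model <- function(n = 20L, p_correct = 0.54, uplift = 0.17,
                             uplift_scale = c("probability", "logodds"),
                             seed = 1L) {
  uplift_scale <- match.arg(uplift_scale)
  if (any(p_correct < 0 | p_correct > 1))
    config_error("respondent_model: p_correct must lie in [0, 1]")
  structure(list(n = pos_int(n, "n", "respondent_model"),
                 p_correct = p_correct, uplift = uplift,
                 uplift_scale = uplift_scale, seed = seed),
            class = "respondent_model")
}

post_probability <- function(model, p_pre) {
  if (model$uplift_scale == "probability") {
    clamp(p_pre + model$uplift, 0, 1)
  } else {
    stats::plogis(stats::qlogis(clamp(p_pre, 1e-12, 1 - 1e-12)) + model$uplift)
  }
}

#' Generate paired pre/post knowledge-test response sheets
#'
#' Each respondent answers every item at both timepoints. A correct
#' answer uses the item's correct option; an incorrect one is drawn
#' uniformly from the remaining options (including "do not know").
#' Reproducible under the model seed.
#'
#' @param model a [respondent_model()].
#' @param spec the multiple-choice instrument definition.
#' @return list with `pre` and `post` (lists of [response_sheet()]s) and
#'   `long` (a long-format data frame as read by [read_responses()]).
#' @export
generate_respondents <- function(model, spec = load_instrument("pakppm")) {
  if (!inherits(model, "respondent_model"))
    config_error("generate_respondents: model must be a respondent_model")
  k <- length(spec$items)
  p_pre <- rep_len(model$p_correct, k)
  p_post <- post_probability(model, p_pre)
  options <- letters[seq_len(spec$n_options)]
  item_ids <- names(spec$items)

  draw_sheet <- function(rid, p, timepoint) {
    ans <- vapply(seq_len(k), function(i) {
      correct <- spec$items[[i]]$correct
      if (runif(1) < p[i]) return(correct)
      wrong <- setdiff(options, correct)
      wrong[1L + floor(runif(1) * length(wrong))]
    }, "")
    response_sheet(rid, spec$name, stats::setNames(as.list(ans), item_ids),
                   timepoint)
  }

  res <- with_rng(rng_state(model$seed), function() {
    pre <- lapply(seq_len(model$n), function(r)
      draw_sheet(sprintf("R%02d", r), p_pre, "pre"))
    post <- lapply(seq_len(model$n), function(r)
      draw_sheet(sprintf("R%02d", r), p_post, "post"))
    list(pre = pre, post = post)
  })$value

  long <- do.call(rbind, lapply(c(res$pre, res$post), function(sh)
    data.frame(respondent = sh$respondent, instrument = sh$instrument,
               timepoint = sh$timepoint, item = names(sh$answers),
               answer = unlist(sh$answers), stringsAsFactors = FALSE)))
  rownames(long) <- NULL
  c(res, list(long = long))
}

#' Generate synthetic Likert / semantic-differential sheets
#'
#' Responses are a Gaussian `N(mean, sd)` rounded to the nearest step
#' and truncated to the item scale.
#'
#' @param n respondents.
#' @param spec instrument definition (`likert` or `semantic_differential`).
#' @param item_mean,item_sd Gaussian parameters on the raw response
#'   scale; defaults to the scale midpoint and a quarter of the range.
#' @param seed generator seed.
#' @return list of [response_sheet()]s.
#' @export
generate_likert_respondents <- function(n, spec, item_mean = NULL,
                                        item_sd = NULL, seed = 1L) {
  if (!spec$type %in% c("likert", "semantic_differential"))
    config_error("generate_likert_respondents: unsupported instrument type '%s'",
                 spec$type)
  rng <- (spec$scale_max - spec$scale_min)
  item_mean <- item_mean %||% (spec$scale_min + rng / 2)
  item_sd <- item_sd %||% (rng / 4)
  item_ids <- names(spec$items)
  with_rng(rng_state(seed), function() {
    lapply(seq_len(n), function(r) {
      raw <- clamp(round(rnorm(length(item_ids), item_mean, item_sd)),
                   spec$scale_min, spec$scale_max)
      response_sheet(sprintf("R%02d", r), spec$name,
                     stats::setNames(as.list(raw), item_ids))
    })
  })$value
}

#' Score generated knowledge sheets and run the pre/post comparison
#'
#' The full evaluation pipeline on synthetic data: score every sheet as
#' percent correct, then compare timepoints with the signed-rank test.
#'
#' @param model a [respondent_model()].
#' @param spec the knowledge-test definition.
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return list with `scores_pre`, `scores_post` (named vectors, percent)
#'   and `comparison` (see [compare_prepost()]).
#' @export
prepost_pipeline <- function(model, spec = load_instrument("pakppm"), ...) {
  gen <- generate_respondents(model, spec)
  score_all <- function(sheets) {
    s <- vapply(sheets, function(sh) score_proportion_correct(sh, spec)$percent,
                numeric(1))
    stats::setNames(s, vapply(sheets, `[[`, "", "respondent"))
  }
  pre <- score_all(gen$pre)
  post <- score_all(gen$post)
  list(scores_pre = pre, scores_post = post,
       comparison = compare_prepost(pre, post, ...))
}
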