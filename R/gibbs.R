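# Latent exponential augmentation and the closed-form Gamma full conditional
# for cluster worths at a fixed partition. One latent variable is attached to
# every ranking stage with a non-trivial denominator; its exponential rate is
# exactly that stage's BTL denominator, the sum of worths of the objects
# still remaining. After augmentation the full conditional of each cluster
# worth is Gamma with
#   shape = a + (number of stages whose selected object lies in the cluster)
#   rate  = b + sum over stages of latent * (cluster members still remaining)
# so worth sampling is exact and loop-free.

# shared core: one augmentation + Gamma draw sweep on a prebuilt stage index
gibbs_once <- function(idx, state, hyper) {
  K <- state$partition$K
  g <- state$partition$assignment
  if (is.null(idx) || idx$n_stages == 0L) {
    shape <- rep(hyper$a, K)
    rate <- rep(hyper$b, K)
  } else {
    d <- stage_denominators(idx, state$expanded)
    y <- rexp(idx$n_stages, rate = d)
    tobj <- object_totals(idx, y)
    shape <- hyper$a + as.vector(rowsum(idx$n_wins, g))
    rate <- hyper$b + as.vector(rowsum(tobj, g))
  }
  repeat {
    lam <- rgamma(K, shape = shape, rate = rate)
    if (all(lam > 0) && !anyDuplicated(lam)) break
  }
  worth_state(state$partition, lam)
}

#' Sample the latent exponential augmentation variables
#'
#' Draws one independent latent `y` per ranking stage with a non-trivial
#' denominator, `y ~ Exponential(rate = sum of worths of the objects still
#' remaining at that stage)`.
#'
#' @param data An [ranking_dataset()].
#' @param worths Strictly positive worth vector of length `J`.
#' @return An object of class `"rcbtl_latents"`: vectors `y` (latent values),
#'   `rate` (their exponential rates), and `judge` (the observation each
#'   stage belongs to).
#' @export
sample_latents <- function(data, worths) {
  if (any(!is.finite(worths)) || any(worths <= 0)) {
    stop("worths must be strictly positive and finite")
  }
  idx <- stage_index(data)
  d <- stage_denominators(idx, worths)
  structure(
    list(y = rexp(idx$n_stages, rate = d), rate = d, judge = idx$obs_id),
    class = "rcbtl_latents"
  )
}

#' Gamma full-conditional parameters of the cluster worths
#'
#' Given the partition, the data, and a draw of the latent augmentation
#' variables, returns the shape and rate of the closed-form Gamma full
#' conditional of each cluster worth. With no data every cluster keeps its
#' prior `(a, b)`.
#'
#' @param p An [partition()].
#' @param data An [ranking_dataset()].
#' @param latents Output of [sample_latents()] for the same data.
#' @param hyper An [rc_hyper()].
#' @return List with numeric vectors `shape` and `rate` of length `K`.
#' @export
full_conditional_params <- function(p, data, latents, hyper) {
  idx <- stage_index(data)
  K <- p$K
  if (idx$n_stages == 0L) {
    return(list(shape = rep(hyper$a, K), rate = rep(hyper$b, K)))
  }
  if (length(latents$y) != idx$n_stages) {
    stop("latents are inconsistent with the dataset")
  }
  tobj <- object_totals(idx, latents$y)
  list(shape = hyper$a + as.vector(rowsum(idx$n_wins, p$assignment)),
       rate = hyper$b + as.vector(rowsum(tobj, p$assignment)))
}

#' Augmented Gibbs update of cluster worths at fixed partition
#'
#' Repeats `n_aug` times: sample fresh latents given the current worths, then
#' draw every cluster worth from its Gamma full conditional. The partition is
#' unchanged. Latents are regenerated on every call and never persisted
#' across partition moves, so the reversible-jump acceptance ratio is always
#' evaluated on the non-augmented posterior.
#'
#' @param state An [worth_state()].
#' @param data An [ranking_dataset()], or `NULL` for prior-only updates.
#' @param hyper An [rc_hyper()].
#' @param n_aug Number of augmentation sweeps.
#' @return The updated [worth_state()].
#' @export
worth_gibbs_update <- function(state, data, hyper, n_aug = 1L) {
  idx <- if (is.null(data)) NULL else stage_index(data)
  for (r in seq_len(n_aug)) state <- gibbs_once(idx, state, hyper)
  state
}
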