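#' Build the three-condition task schedule
#'
#' Constructs the fixed trial sequence of the probabilistic learning task:
#' three trial types (reward, neutral, loss), `n_per_type` trials each,
#' pseudo-randomly interleaved with a sequence fixed by `seed` - emulating a
#' predetermined sequence shared by all subjects.  Each type uses one fractal
#' pair; on reward and loss pairs the better option carries a 70% favourable
#' contingency (win on reward trials, avoid-loss on loss trials) and the
#' worse option 30%.  Sides are randomized per trial, and each trial carries
#' a jittered inter-stimulus interval drawn uniformly from 3 to 13.75 s,
#' recorded for event-file export only.
#'
#' @param seed integer seed fixing the sequence.
#' @param n_per_type trials per trial type (default 60, giving 180 in total).
#' @param good_option_prob probability of the favourable outcome for the
#'   better option of the reward and loss pairs (default 0.7).
#' @return a `task_schedule` data frame with one row per trial: `trial`,
#'   `trial_type`, `within_type_index`, `pair_id`, `good_option_prob`,
#'   `bad_option_prob`, `side_better`, `isi_s`.
#' @examples
#' sched <- build_schedule(seed = 1)
#' table(sched$trial_type)
#' @export
build_schedule <- function(seed, n_per_type = 60, good_option_prob = 0.7) {
  if (!is.numeric(n_per_type) || n_per_type < 1)
    stop("n_per_type must be a positive integer")
  n_per_type <- as.integer(n_per_type)
  types <- c("reward", "neutral", "loss")
  out <- local_seed(seed, {
    ord <- sample(rep(types, each = n_per_type))
    n <- length(ord)
    data.frame(
      trial = seq_len(n),
      trial_type = factor(ord, levels = types),
      within_type_index = stats::ave(seq_len(n), ord, FUN = seq_along),
      pair_id = paste0("pair_", match(ord, types)),
      good_option_prob = ifelse(ord == "neutral", NA_real_, good_option_prob),
      bad_option_prob = ifelse(ord == "neutral", NA_real_,
                               1 - good_option_prob),
      side_better = sample(c("left", "right"), n, replace = TRUE),
      isi_s = runif(n, 3, 13.75)
    )
  })
  attr(out, "seed") <- seed
  attr(out, "n_per_type") <- n_per_type
  class(out) <- c("task_schedule", "data.frame")
  out
}

# evaluate `expr` under a local RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

schedule_to_int <- function(schedule) {
  list(type = match(as.character(schedule$trial_type),
                    c("reward", "neutral", "loss")) - 1L,
       tt = as.integer(schedule$within_type_index))
}

#' Sample a single trial outcome
#'
#' Applies the task contingencies to one trial: on reward trials the chosen
#' option wins (+1) with its win probability, otherwise 0; on loss trials it
#' loses (-1) with its loss probability, otherwise 0; neutral trials always
#' return 0.  The better option carries the 70% favourable contingency (70%
#' win on reward trials, only 30% loss on loss trials).
#'
#' @param trial one row of a [build_schedule()] data frame (or any list with
#'   `trial_type` and `good_option_prob`).
#' @param choice `"better"`, `"worse"`, or `"omitted"`.
#' @param rng_seed integer seed.
#' @return the reinforcement (+1, 0 or -1), or `NA` for an omitted choice.
#' @examples
#' sched <- build_schedule(1)
#' sample_outcome(sched[sched$trial_type == "reward", ][1, ], "better", 42)
#' @export
sample_outcome <- function(trial, choice, rng_seed) {
  choice <- match.arg(choice, c("better", "worse", "omitted"))
  if (choice == "omitted") return(NA_real_)
  type <- as.character(trial$trial_type)
  if (type == "neutral") return(0)
  gp <- trial$good_option_prob
  local_seed(rng_seed, {
    u <- runif(1)
    if (type == "reward") {
      pw <- if (choice == "better") gp else 1 - gp
      if (u < pw) 1 else 0
    } else {
      pl <- if (choice == "better") 1 - gp else gp
      if (u < pl) -1 else 0
    }
  })
}
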