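# Go/Nogo task-schedule generator.

#' Generate a pseudorandomized Go/Nogo task schedule
#'
#' Emits the trial list of a two-condition Go/Nogo experiment: by default 196
#' Go and 84 Nogo trials per feature-overlap condition (a 70:30 Go-to-Nogo
#' ratio), split over 7 equally sized blocks with trials shuffled within each
#' block, 450 ms stimuli, a 1700 ms response deadline, and inter-trial
#' intervals drawn uniformly from 700-1100 ms.
#'
#' @param seed Integer seed; the schedule is reproducible from it.
#' @param blocks Number of equally sized blocks (must divide the total trial
#'   count; default 7).
#' @param go_per_condition,nogo_per_condition Trials per overlap condition.
#' @param iti_range_ms Inter-trial interval range in ms.
#' @param stimulus_duration_ms,response_deadline_ms Timing constants in ms.
#' @return A tibble with one row per trial: `trial`, `block`, `trial_type`
#'   (`"Go"`/`"Nogo"`), `overlap` (`"overlapping"`/`"non-overlapping"`),
#'   `iti_ms`, `stimulus_duration_ms`, `response_deadline_ms`.
#' @export
#' @examples
#' sched <- make_task_schedule(seed = 1)
#' table(sched$trial_type, sched$overlap)
make_task_schedule <- function(seed = NULL, blocks = 7,
                               go_per_condition = 196, nogo_per_condition = 84,
                               iti_range_ms = c(700, 1100),
                               stimulus_duration_ms = 450,
                               response_deadline_ms = 1700) {
  total <- 2L * (go_per_condition + nogo_per_condition)
  if (total %% blocks != 0) {
    abort(sprintf("block count %d does not divide the total trial count %d.", blocks, total))
  }
  overlaps <- c("overlapping", "non-overlapping")
  cells <- expand.grid(
    trial_type = c("Go", "Nogo"), overlap = overlaps,
    stringsAsFactors = FALSE
  )
  cells$n <- ifelse(cells$trial_type == "Go", go_per_condition, nogo_per_condition)

  with_seed_if(seed, {
    # distribute each cell as evenly as possible over blocks (remainders to
    # randomly chosen blocks), then shuffle within block
    block_of <- vector("list", nrow(cells))
    for (k in seq_len(nrow(cells))) {
      base <- cells$n[k] %/% blocks
      rem <- cells$n[k] %% blocks
      counts <- rep(base, blocks)
      if (rem > 0) {
        extra <- sample.int(blocks, rem)
        counts[extra] <- counts[extra] + 1L
      }
      block_of[[k]] <- rep(seq_len(blocks), counts)
    }
    df <- tibble(
      trial_type = rep(cells$trial_type, cells$n),
      overlap = rep(cells$overlap, cells$n),
      block = unlist(block_of)
    )
    df <- df[order(df$block, runif(nrow(df))), ]
    df$trial <- seq_len(nrow(df))
    df$iti_ms <- runif(nrow(df), iti_range_ms[1], iti_range_ms[2])
    df$stimulus_duration_ms <- stimulus_duration_ms
    df$response_deadline_ms <- response_deadline_ms
    df[, c(
      "trial", "block", "trial_type", "overlap", "iti_ms",
      "stimulus_duration_ms", "response_deadline_ms"
    )]
  })
}
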