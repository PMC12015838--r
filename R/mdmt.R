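# Moral Decision-Making Task (MDMT) schedule preset.
#
# The packaged worked example: a 56-dilemma audio-visual moral
# decision-making session.  Each dilemma is ISI (1 s) -> audio stimulus
# (normal, 27.8 +/- 3.00 s) -> ISI (1 s) -> choice window (normal,
# 4.34 +/- 2.01 s, truncated below at 0.5 s by rejection sampling); a 30-s
# break follows every 7th dilemma.  The dilemma inventory is one non-moral
# block of eight plus six condition-by-variation blocks of eight: personal
# (MP) and impersonal (MI) moral conditions, each under unobserved (U),
# media (M) and authority (A) observation variations; presentation order is
# shuffled under the seed.

#' MDMT event schedule
#'
#' Builds the event list of one simulated MDMT session: per dilemma an
#' `isi`, `audio_<cond>_<k>`, `isi`, `choice_<cond>_<k>` chain (epoch names
#' carry condition and variation), `pause` events after every
#' `pause_after`-th dilemma, and a final `end` terminator.
#'
#' @param n_dilemmas number of dilemmas (default 56 = 8 non-moral + 6 x 8
#'   condition x variation; other counts recycle the inventory).
#' @param isi_s inter-stimulus interval (s).
#' @param audio_mean_s,audio_sd_s audio stimulus duration model (s).
#' @param choice_mean_s,choice_sd_s choice window duration model (s).
#' @param choice_min_s lower truncation of the choice window (s).
#' @param pause_after insert a pause after every this many dilemmas.
#' @param pause_s pause length (s).
#' @param seed integer seed for durations and presentation order.
#' @return list with `events` (data.frame `name`, `t_s`), `dilemmas`
#'   (data.frame `index`, `condition`, `variation`, `audio_s`, `choice_s`)
#'   and `duration_s` (session length).
#' @export
mdmt_schedule <- function(n_dilemmas = 56, isi_s = 1,
                          audio_mean_s = 27.8, audio_sd_s = 3.00,
                          choice_mean_s = 4.34, choice_sd_s = 2.01,
                          choice_min_s = 0.5, pause_after = 7,
                          pause_s = 30, seed = 1L) {
  stopifnot(n_dilemmas >= 1)
  set.seed(as.integer(seed))
  inventory <- rbind(
    data.frame(condition = "NM", variation = "-", stringsAsFactors = FALSE),
    expand.grid(condition = c("MP", "MI"), variation = c("U", "A", "M"),
                stringsAsFactors = FALSE)
  )
  blocks <- inventory[rep(seq_len(nrow(inventory)), each = 8L), ]
  order_idx <- sample(nrow(blocks))
  dilemmas <- blocks[rep_len(order_idx, n_dilemmas), , drop = FALSE]
  dilemmas$index <- seq_len(n_dilemmas)
  rownames(dilemmas) <- NULL

  dilemmas$audio_s <- pmax(stats::rnorm(n_dilemmas, audio_mean_s,
                                        audio_sd_s), 1)
  choice <- numeric(n_dilemmas)
  for (i in seq_len(n_dilemmas)) {   # truncated normal by rejection
    repeat {
      v <- stats::rnorm(1, choice_mean_s, choice_sd_s)
      if (v >= choice_min_s) break
    }
    choice[i] <- v
  }
  dilemmas$choice_s <- choice

  name <- character()
  t_s <- numeric()
  t <- 0
  push <- function(nm, at) {
    name <<- c(name, nm)
    t_s <<- c(t_s, at)
  }
  for (i in seq_len(n_dilemmas)) {
    tag <- sprintf("%s_%s_%02d", dilemmas$condition[i],
                   sub("-", "x", dilemmas$variation[i]), i)
    push("isi", t); t <- t + isi_s
    push(paste0("audio_", tag), t); t <- t + dilemmas$audio_s[i]
    push("isi", t); t <- t + isi_s
    push(paste0("choice_", tag), t); t <- t + dilemmas$choice_s[i]
    if (i %% pause_after == 0L && i < n_dilemmas) {
      push("pause", t); t <- t + pause_s
    }
  }
  push("end", t)
  # both second-scale (generator config) and ns-scale (epoch builder) times
  list(events = data.frame(name = name, t_s = t_s, ts = s_to_ns(t_s),
                           stringsAsFactors = FALSE),
       dilemmas = dilemmas, duration_s = t)
}

#' Simulation configuration preset for an MDMT session
#'
#' Wraps [mdmt_schedule()] into a [simulation_config()] whose events and
#' duration follow the schedule; remaining generator parameters keep their
#' defaults unless overridden via `...`.
#'
#' @param seed integer seed shared by the schedule and the generator.
#' @param n_dilemmas number of dilemmas.
#' @param ... further arguments to [simulation_config()].
#' @return a `simulation_config` with a `mdmt` attribute holding the
#'   schedule (events, dilemma inventory, planted durations).
#' @export
mdmt_config <- function(seed = 1L, n_dilemmas = 56, ...) {
  sched <- mdmt_schedule(n_dilemmas = n_dilemmas, seed = seed)
  cfg <- simulation_config(duration_s = sched$duration_s,
                           events = sched$events, seed = seed, ...)
  attr(cfg, "mdmt") <- sched
  cfg
}
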