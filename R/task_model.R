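#' Generate a counterbalanced Go/NoGo trial schedule
#'
#' Builds the full stimulus/response plan of one session of the executive
#' reaction time task: a sequence of trials where a white triangle (pointing
#' up or down) must be held in working memory, followed 150 ms after its
#' offset by a traffic-light cue whose colour signals Go (respond according
#' to the memorized orientation) or NoGo (withhold), with a task-irrelevant
#' emotional or neutral distractor superimposed on the cue.
#'
#' Counterbalancing is exact over the whole schedule: Go vs NoGo cues,
#' emotional vs neutral distractors and up vs down orientations each occur in
#' a 50:50 ratio, with the Go/NoGo x distractor crossing balanced exactly.
#' Half of the blocks use the reversed traffic-light rule (green = NoGo,
#' red = Go) and half are performed with the left hand; trial order is
#' randomized within blocks under the given seed.
#'
#' @param n_blocks Number of blocks (must be even so that rule and hand can
#'   each be assigned to exactly half of the blocks). Default 16.
#' @param trials_per_block Trials in each block (must be divisible by 4 so
#'   the cue x distractor crossing balances exactly). Default 64.
#' @param seed Integer seed; the same seed reproduces the identical schedule.
#' @param iti_ms Inter-trial onset interval in ms (time between consecutive
#'   trial onsets). The task timing within a trial is fixed: triangle at
#'   0--150 ms, cue (and distractor) onset at 300 ms. Default 2600.
#' @param cue_duration_ms Duration of the traffic-light cue and distractor
#'   in ms. Default 300.
#'
#' @return An object of class \code{trial_schedule}: a data frame with one
#'   row per trial and columns \code{block}, \code{trial}, \code{orientation}
#'   (\code{"up"}/\code{"down"}), \code{cue_color} (\code{"green"}/
#'   \code{"red"}), \code{rule} (\code{"normal"}/\code{"reversed"}),
#'   \code{cue} (\code{"go"}/\code{"nogo"}, derived from colour and rule),
#'   \code{distractor} (\code{"emotional"}/\code{"neutral"}), \code{hand},
#'   and the timing columns \code{t_triangle_on} (0), \code{t_triangle_off}
#'   (150) and \code{t_cue_on} (300), all in ms from trial onset. Attributes
#'   \code{n_blocks}, \code{trials_per_block}, \code{seed}, \code{iti_ms} and
#'   \code{cue_duration_ms} record the design.
#' @examples
#' sched <- generate_schedule(2, 8, seed = 1)
#' table(sched$cue, sched$distractor)
#' @export
generate_schedule <- function(n_blocks = 16L, trials_per_block = 64L,
                              seed = 1L, iti_ms = 2600,
                              cue_duration_ms = 300) {
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_blocks < 2L || n_blocks %% 2L != 0L)
    stop("balance infeasible: n_blocks must be even (rule and hand are ",
         "assigned to half of the blocks each)")
  if (trials_per_block %% 4L != 0L)
    stop("balance infeasible: trials_per_block must be divisible by 4 ",
         "(exact 50:50 crossing of cue x distractor)")

  n_total <- n_blocks * trials_per_block

  # Exact global balance: each (cue, distractor) cell appears n_total / 4
  # times, orientation 50:50 crossed within each cell so the three marginal
  # 50:50 balances hold exactly whatever the shuffling does.
  cell <- expand.grid(cue = c("go", "nogo"),
                      distractor = c("emotional", "neutral"),
                      orientation = c("up", "down"),
                      stringsAsFactors = FALSE)
  reps <- n_total / nrow(cell)  # n_total divisible by 8: tpb %% 4 == 0, blocks even
  pool <- cell[rep(seq_len(nrow(cell)), each = reps), ]

  withr_seed <- function(expr) {  # local RNG, leave global stream untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(as.integer(seed))
    expr
  }

  withr_seed({
    pool <- pool[sample.int(nrow(pool)), ]
    # blocks: half reversed rule, half left hand, assignments randomized
    rule_blocks <- sample(rep(c("normal", "reversed"), n_blocks / 2L))
    hand_blocks <- sample(rep(c("right", "left"), n_blocks / 2L))
    sched <- data.frame(
      block = rep(seq_len(n_blocks), each = trials_per_block),
      trial = rep(seq_len(trials_per_block), times = n_blocks),
      orientation = pool$orientation,
      rule = rep(rule_blocks, each = trials_per_block),
      cue = pool$cue,
      distractor = pool$distractor,
      hand = rep(hand_blocks, each = trials_per_block),
      stringsAsFactors = FALSE
    )
  })

  # The traffic light colour is what is displayed; its Go/NoGo meaning
  # derives from the block rule (normal: green = Go; reversed: green = NoGo).
  sched$cue_color <- ifelse(
    (sched$cue == "go") == (sched$rule == "normal"), "green", "red")
  sched$t_triangle_on <- 0
  sched$t_triangle_off <- 150
  sched$t_cue_on <- 300
  sched <- sched[, c("block", "trial", "orientation", "cue_color", "rule",
                     "cue", "distractor", "hand",
                     "t_triangle_on", "t_triangle_off", "t_cue_on")]
  attr(sched, "n_blocks") <- n_blocks
  attr(sched, "trials_per_block") <- trials_per_block
  attr(sched, "seed") <- as.integer(seed)
  attr(sched, "iti_ms") <- iti_ms
  attr(sched, "cue_duration_ms") <- cue_duration_ms
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Cue meaning from traffic-light colour and block rule
#'
#' Under the normal rule a green light means Go and a red light NoGo;
#' in reversed-rule blocks the mapping flips.
#'
#' @param cue_color \code{"green"} or \code{"red"} (vectorized).
#' @param rule \code{"normal"} or \code{"reversed"} (vectorized).
#' @return \code{"go"} or \code{"nogo"}.
#' @export
cue_meaning <- function(cue_color, rule) {
  stopifnot(all(cue_color %in% c("green", "red")),
            all(rule %in% c("normal", "reversed")))
  ifelse((cue_color == "green") == (rule == "normal"), "go", "nogo")
}

#' Required response for a trial
#'
#' The correct response is no press on NoGo trials; on Go trials the button
#' corresponds to the memorized triangle orientation: up = middle finger,
#' down = index finger.
#'
#' @param trial A one-row data frame (or a \code{trial_schedule}) with
#'   columns \code{cue} and \code{orientation}; vectorized over rows.
#' @return Character vector in \code{c("index", "middle", "none")}.
#' @examples
#' s <- generate_schedule(2, 4, seed = 1)
#' required_response(s)
#' @export
required_response <- function(trial) {
  stopifnot(all(trial$cue %in% c("go", "nogo")),
            all(trial$orientation %in% c("up", "down")))
  ifelse(trial$cue == "nogo", "none",
         ifelse(trial$orientation == "up", "middle", "index"))
}

#' Classify trial outcomes from responses
#'
#' Maps each (trial, response) pair to one of the task's outcome kinds:
#' \itemize{
#'   \item \code{correct}: the required button on Go, or no press on NoGo;
#'   \item \code{miss}: no press on a Go trial;
#'   \item \code{incorrect_button}: the wrong button on a Go trial
#'     (a working-memory lapse);
#'   \item \code{commission}: any press on a NoGo trial (a response-inhibition
#'     failure, the "NoGo error").
#' }
#'
#' @param trial A \code{trial_schedule} (or compatible data frame) with
#'   columns \code{cue} and \code{orientation}.
#' @param response A data frame with logical \code{pressed} and character
#'   \code{button} (\code{"index"}, \code{"middle"} or \code{"none"}); rows
#'   aligned with \code{trial}. \code{pressed = FALSE} implies
#'   \code{button = "none"}.
#' @return Character vector of outcome kinds.
#' @export
classify_outcome <- function(trial, response) {
  stopifnot(nrow(trial) == nrow(response),
            is.logical(response$pressed),
            all(response$button %in% c("index", "middle", "none")))
  if (any(!response$pressed & response$button != "none"))
    stop("malformed response: pressed = FALSE requires button = 'none'")
  if (any(response$pressed & response$button == "none"))
    stop("malformed response: pressed = TRUE requires a button")
  req <- required_response(trial)
  out <- character(nrow(trial))
  nogo <- trial$cue == "nogo"
  out[nogo & response$pressed] <- "commission"
  out[nogo & !response$pressed] <- "correct"
  go <- !nogo
  out[go & !response$pressed] <- "miss"
  out[go & response$pressed & response$button == req] <- "correct"
  out[go & response$pressed & response$button != req &
        response$button != "none"] <- "incorrect_button"
  out
}

#' Marker code table for the four ERP conditions
#'
#' Fixed mapping between event-marker integer codes in the EEG stream and
#' the cue x distractor condition cells.
#'
#' @return Data frame with columns \code{code}, \code{cue}, \code{distractor}
#'   and \code{condition} (e.g. \code{"GoEmotional"}).
#' @export
condition_codes <- function() {
  data.frame(
    code = 1:4,
    cue = c("go", "go", "nogo", "nogo"),
    distractor = c("emotional", "neutral", "emotional", "neutral"),
    condition = c("GoEmotional", "GoNeutral", "NoGoEmotional", "NoGoNeutral"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d blocks x %d trials (%d total), seed %d\n",
              attr(x, "n_blocks"), attr(x, "trials_per_block"), nrow(x),
              attr(x, "seed")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write / read a trial schedule as delimited text
#'
#' One row per trial with a header line; tab-separated. Design attributes
#' are stored in comment lines (\code{# key value}) above the header.
#'
#' @param schedule A \code{trial_schedule}.
#' @param path File path.
#' @return \code{write_schedule} returns \code{path} invisibly;
#'   \code{read_schedule} returns the \code{trial_schedule}.
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("n_blocks", "trials_per_block", "seed", "iti_ms",
                "cue_duration_ms"))
    writeLines(sprintf("# %s %s", key, attr(schedule, key)), con)
  utils::write.table(as.data.frame(schedule), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- do.call(rbind, strsplit(sub("^# ", "", hdr), " "))
  sched <- utils::read.table(path, sep = "\t", header = TRUE,
                             comment.char = "#", stringsAsFactors = FALSE)
  vals <- stats::setNames(as.numeric(meta[, 2]), meta[, 1])
  for (key in names(vals))
    attr(sched, key) <- if (key %in% c("iti_ms", "cue_duration_ms"))
      vals[[key]] else as.integer(vals[[key]])
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}
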