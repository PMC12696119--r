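#' Select a target and three graded foils from a ten-image scale
#'
#' From a normalized ten-image perceptual scale, picks the anchor-end image
#' (scale value 0) as the memory target and chooses three foils whose
#' embedding distances from the target are as close as possible to the
#' equispaced ladder `j * span / 3`, `j = 1..3`, with `span` the largest
#' scale distance from the target. All `choose(9, 3) = 84` subsets are
#' scored exhaustively, so the selection is exactly optimal; ties go to the
#' lowest indices (with a warning when duplicate scale values make the gap
#' ordering non-strict). Foils are returned hard to easy: the nearest foil
#' is the hardest to discriminate from the target.
#'
#' @param psi_hat an `"embedding_scale"` or a normalized numeric scale of
#'   length 10 (min 0, max 1).
#' @return a `"foil_set"` list: `target_idx`, `foil_idxs` (hard, medium,
#'   easy), `gaps` (increasing target–foil scale distances),
#'   `objective_value`.
#' @export
select_foils <- function(psi_hat) {
  psi <- if (inherits(psi_hat, "embedding_scale")) psi_hat$psi_hat else psi_hat
  if (!is.null(dim(psi))) stop("foil selection requires a 1-D scale")
  if (length(psi) != 10L) stop("expected a ten-image scale")
  if (abs(min(psi)) > 1e-9 || abs(max(psi) - 1) > 1e-9) {
    stop("scale must be normalized to [0, 1] (see normalize_embedding)")
  }
  target <- which.min(psi)
  cand <- setdiff(seq_along(psi), target)
  gaps_all <- abs(psi[cand] - psi[target])
  span <- max(gaps_all)
  ladder <- seq_len(3) * span / 3

  subsets <- utils::combn(length(cand), 3)
  best <- NULL
  for (s in seq_len(ncol(subsets))) {
    pick <- subsets[, s]
    g <- sort(gaps_all[pick])
    val <- sum((g - ladder)^2)
    if (is.null(best) || val < best$val - 1e-15) {
      best <- list(val = val, pick = pick)
    }
  }
  pick <- cand[best$pick]
  ord <- order(gaps_all[best$pick], pick)  # hard -> easy, index tie-break
  foils <- pick[ord]
  gaps <- abs(psi[foils] - psi[target])
  if (anyDuplicated(round(psi, 12)) || any(diff(gaps) <= 0)) {
    warning("duplicate scale values: foil gaps may not be strictly ",
            "increasing; ties broken by lowest index")
  }
  structure(
    list(target_idx = target, foil_idxs = foils, gaps = gaps,
         objective_value = best$val),
    class = "foil_set"
  )
}

#' @export
print.foil_set <- function(x, ...) {
  cat(sprintf("target = image %d; foils (hard, medium, easy) = %s; gaps = %s\n",
              x$target_idx, paste(x$foil_idxs, collapse = ", "),
              paste(format(round(x$gaps, 3)), collapse = ", ")))
  invisible(x)
}

# a uniformly scrambled 3x3 Latin square (rows = target groups,
# cols = blocks within a half, entries = difficulty levels)
random_latin3 <- function() {
  L <- outer(0:2, 0:2, function(i, j) (i + j) %% 3) + 1
  L <- L[sample(3), sample(3)]
  matrix(sample(3)[L], 3, 3)
}

#' Generate a delayed match-to-sample memory session
#'
#' Builds one participant's 108-trial session: six blocks of 18 trials, each
#' block holding the participant's nine repeated targets (every repeated
#' target once per block) and nine of the 54 non-repeated targets (each used
#' exactly once in the session). Difficulty (easy / medium / hard, i.e.
#' which foil opposes the target) is balanced at three trials per level
#' within each block for both conditions, and every repeated target runs
#' through all three difficulties in random order within blocks 1–3 and
#' again within blocks 4–6, so object-specific difficulty is fully
#' counterbalanced every three blocks. Whether the target appears first or
#' second, and on which side the response option "one" is displayed, are
#' each split exactly 54/54 and crossed 27 per cell, which also equates the
#' two response buttons' correct-answer counts. The inter-trial interval is
#' drawn from 1000/1500/2000 ms.
#'
#' @param repeated_ids 9 object ids serving as repeated targets.
#' @param nonrepeated_ids 54 object ids serving as non-repeated targets.
#' @param seed integer seed; the session is reproducible from it.
#' @param participant_id participant label.
#' @return a `"memory_session"` data.frame with columns `participant`,
#'   `block`, `trial`, `object_id`, `repeated`, `difficulty`,
#'   `target_position`, `mapping_side`, `iti_ms`.
#' @export
generate_memory_session <- function(repeated_ids, nonrepeated_ids, seed,
                                    participant_id = "P001") {
  repeated_ids <- as.character(repeated_ids)
  nonrepeated_ids <- as.character(nonrepeated_ids)
  if (length(repeated_ids) != 9L) {
    stop("need exactly 9 repeated target ids, got ", length(repeated_ids))
  }
  if (length(nonrepeated_ids) != 54L) {
    stop("need exactly 54 non-repeated target ids, got ", length(nonrepeated_ids))
  }
  if (anyDuplicated(c(repeated_ids, nonrepeated_ids))) {
    stop("target ids must be distinct across roles")
  }
  set_seed_if(seed)
  levels3 <- c("easy", "medium", "hard")

  # repeated targets: difficulty Latin design per half (blocks 1-3, 4-6)
  rep_diff <- matrix(NA_character_, 9, 6)
  for (half in 1:2) {
    groups <- split(sample(9), rep(1:3, each = 3))
    L <- random_latin3()
    for (g in 1:3) {
      for (b in 1:3) {
        rep_diff[groups[[g]], (half - 1) * 3 + b] <- levels3[L[g, b]]
      }
    }
  }

  # non-repeated targets: 9 per block, difficulties 3/3/3 within block
  nonrep_order <- sample(nonrepeated_ids)
  nonrep_block <- rep(1:6, each = 9)

  rows <- vector("list", 6)
  for (b in 1:6) {
    rep_part <- data.frame(object_id = repeated_ids, repeated = TRUE,
                           difficulty = rep_diff[, b])
    nr_ids <- nonrep_order[nonrep_block == b]
    nonrep_part <- data.frame(object_id = nr_ids, repeated = FALSE,
                              difficulty = sample(rep(levels3, each = 3)))
    blk <- rbind(rep_part, nonrep_part)
    blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
    blk$block <- b
    rows[[b]] <- blk
  }
  df <- do.call(rbind, rows)

  # position x side crossed 27 per cell -> exact 54/54 marginals and equal
  # correct-button counts
  cross <- expand.grid(target_position = c("first", "second"),
                       mapping_side = c("left", "right"),
                       stringsAsFactors = FALSE)
  cross <- cross[rep(seq_len(4), each = 27), ]
  cross <- cross[sample.int(108), , drop = FALSE]

  session <- data.frame(
    participant = participant_id,
    block = df$block,
    trial = seq_len(108),
    object_id = df$object_id,
    repeated = df$repeated,
    difficulty = factor(df$difficulty, levels = levels3),
    target_position = cross$target_position,
    mapping_side = cross$mapping_side,
    iti_ms = sample(c(1000L, 1500L, 2000L), 108, replace = TRUE),
    row.names = NULL
  )
  attr(session, "seed") <- seed
  class(session) <- c("memory_session", "data.frame")
  session
}

#' Which response button is correct on a memory trial
#'
#' The correct option is "one" when the target is shown first and "two" when
#' it is shown second; the button is the side that option is mapped to
#' (`mapping_side` gives the side of option "one").
#'
#' @param session a `"memory_session"` data.frame.
#' @return character vector `"left"`/`"right"`.
#' @export
correct_button <- function(session) {
  df <- as.data.frame(session)
  ifelse(df$target_position == "first",
         df$mapping_side,
         ifelse(df$mapping_side == "left", "right", "left"))
}

#' List counterbalancing violations of a memory session
#'
#' Checks every structural invariant of the delayed match-to-sample design
#' and returns a character vector of violations (empty when the session is
#' valid). [validate_memory_session()] is the erroring wrapper.
#'
#' @param session a candidate session data.frame.
#' @return character vector of violation messages.
#' @export
memory_session_violations <- function(session) {
  df <- as.data.frame(session)
  v <- character(0)
  add <- function(v, cond, msg) if (cond) c(v, msg) else v

  v <- add(v, nrow(df) != 108L, sprintf("expected 108 trials, got %d", nrow(df)))
  tb <- table(factor(df$block, levels = 1:6))
  v <- add(v, any(tb != 18L), "blocks must each contain 18 trials")
  v <- add(v, !all(df$difficulty %in% c("easy", "medium", "hard")),
           "invalid difficulty level")
  v <- add(v, !all(df$iti_ms %in% c(1000L, 1500L, 2000L)),
           "inter-trial interval outside {1000, 1500, 2000} ms")
  v <- add(v, !all(df$target_position %in% c("first", "second")),
           "invalid target_position")
  v <- add(v, !all(df$mapping_side %in% c("left", "right")),
           "invalid mapping_side")
  if (length(v)) return(v)

  for (b in 1:6) {
    blk <- df[df$block == b, ]
    v <- add(v, sum(blk$repeated) != 9L || sum(!blk$repeated) != 9L,
             sprintf("block %d: repeated/non-repeated not 9/9", b))
    for (cond in c(TRUE, FALSE)) {
      dt <- table(factor(blk$difficulty[blk$repeated == cond],
                         levels = c("easy", "medium", "hard")))
      v <- add(v, any(dt != 3L),
               sprintf("block %d, %s: difficulties not 3/3/3", b,
                       if (cond) "repeated" else "non-repeated"))
    }
  }

  rep_df <- df[df$repeated, ]
  rep_ids <- unique(rep_df$object_id)
  v <- add(v, length(rep_ids) != 9L, "expected 9 distinct repeated targets")
  for (id in rep_ids) {
    per_block <- table(factor(rep_df$block[rep_df$object_id == id], levels = 1:6))
    v <- add(v, any(per_block != 1L),
             sprintf("repeated target %s not shown once per block", id))
    for (half in list(1:3, 4:6)) {
      dd <- rep_df$difficulty[rep_df$object_id == id & rep_df$block %in% half]
      v <- add(v, !setequal(as.character(dd), c("easy", "medium", "hard")),
               sprintf("repeated target %s: difficulties not counterbalanced in blocks %d-%d",
                       id, half[1], half[3]))
    }
  }
  nr_tab <- table(df$object_id[!df$repeated])
  v <- add(v, any(nr_tab != 1L) || length(nr_tab) != 54L,
           "non-repeated targets must each appear exactly once")

  v <- add(v, sum(df$target_position == "first") != 54L,
           "target_position not split 54/54")
  v <- add(v, sum(df$mapping_side == "left") != 54L,
           "mapping_side not split 54/54")
  v <- add(v, sum(correct_button(df) == "left") != 54L,
           "correct responses not split equally over buttons")
  v
}

#' @rdname memory_session_violations
#' @export
validate_memory_session <- function(session) {
  v <- memory_session_violations(session)
  if (length(v)) {
    stop("invalid memory session:\n  - ", paste(v, collapse = "\n  - "))
  }
  invisible(TRUE)
}

#' Accuracy summary by block, condition and difficulty
#'
#' Aggregates in two steps, the way repeated-measures accuracy is reported:
#' first each participant's mean accuracy per (block, condition, difficulty)
#' cell, then the across-participant mean and standard error
#' (`SEM = SD / sqrt(n_participants)`). Cells with no data are simply absent
#' from the output, never imputed.
#'
#' @param responses data.frame with columns `participant`, `block`,
#'   `repeated`, `difficulty` and logical/0-1 `correct`.
#' @return data.frame with `block`, `repeated`, `difficulty`,
#'   `mean_accuracy`, `sem`, `n_participants`.
#' @export
summarize_accuracy <- function(responses) {
  df <- as.data.frame(responses)
  needed <- c("participant", "block", "repeated", "difficulty", "correct")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) stop("responses missing columns: ", paste(missing, collapse = ", "))
  df$correct <- as.numeric(df$correct)

  pm <- stats::aggregate(correct ~ participant + block + repeated + difficulty,
                         data = df, FUN = mean)
  agg <- stats::aggregate(correct ~ block + repeated + difficulty, data = pm,
                          FUN = function(x) {
                            c(mean = mean(x),
                              sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
                              n = length(x))
                          })
  out <- data.frame(block = agg$block, repeated = agg$repeated,
                    difficulty = agg$difficulty,
                    mean_accuracy = agg$correct[, "mean"],
                    sem = agg$correct[, "sem"],
                    n_participants = as.integer(agg$correct[, "n"]))
  out[order(out$block, !out$repeated, out$difficulty), , drop = FALSE]
}
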