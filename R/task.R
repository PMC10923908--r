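#' Construct a 6-item transitive-inference hierarchy
#'
#' A hierarchy is an ordered list of six items A > B > ... > F belonging to
#' one stimulus category, assigned to one TMR condition, with six
#' experimental sounds (one per item) and six disjoint novel sounds.
#'
#' @param condition one of "Up", "Down", "Control".
#' @param category stimulus category label, e.g. "faces", "scenes", "objects".
#' @param items ordered character vector of exactly 6 unique item ids; the
#'   first item is the highest-ranked.
#' @param experimental_sounds,novel_sounds 6 sound ids each, disjoint sets.
#' @return object of class `hierarchy`.
#' @export
hierarchy <- function(condition, category, items = LETTERS[1:6],
                      experimental_sounds = paste0(category, "_exp", 1:6),
                      novel_sounds = paste0(category, "_nov", 1:6)) {
  if (length(items) != 6 || anyDuplicated(items))
    stop("hierarchy needs exactly 6 unique items")
  if (!condition %in% c("Up", "Down", "Control"))
    stop("condition must be Up, Down or Control")
  if (length(experimental_sounds) != 6 || length(novel_sounds) != 6)
    stop("need 6 experimental and 6 novel sounds")
  if (length(intersect(experimental_sounds, novel_sounds)))
    stop("experimental and novel sound sets must be disjoint")
  structure(list(condition = condition, category = category, items = items,
                 experimental_sounds = experimental_sounds,
                 novel_sounds = novel_sounds),
            class = "hierarchy")
}

#' Adjacent premise pairs of a hierarchy
#'
#' For items A > B > C > D > E > F the premise pairs are A>B, B>C, C>D, D>E,
#' E>F; the higher-ranked item is always correct.
#'
#' @param h a [hierarchy()].
#' @return data.frame with columns `item_hi`, `item_lo`, `correct`,
#'   `pair_class` = "premise".
#' @export
build_premise_pairs <- function(h) {
  stopifnot(inherits(h, "hierarchy"))
  data.frame(item_hi = h$items[1:5], item_lo = h$items[2:6],
             correct = h$items[1:5], pair_class = "premise",
             stringsAsFactors = FALSE)
}

#' Degree of separation of a pair within a hierarchy
#'
#' Number of items intervening between the two pair members in the hierarchy
#' order: 0 for adjacent (premise) pairs, 1 for B-D, 2 for B-E, etc.
#'
#' @param pair character vector of two item ids.
#' @param h a [hierarchy()].
#' @return non-negative integer.
#' @export
degree_of_separation <- function(pair, h) {
  stopifnot(inherits(h, "hierarchy"))
  idx <- match(pair, h$items)
  if (anyNA(idx)) stop("pair contains an item not in the hierarchy")
  abs(diff(idx)) - 1L
}

#' Late-test pair set (premise + inference + anchor)
#'
#' The morning/follow-up test presents 9 pairs per hierarchy: the 5 learned
#' premise pairs, 3 novel inference pairs (B>D and C>E at 1st degree of
#' separation, B>E at 2nd degree), and the anchor pair A>F (solvable without
#' inference because A is always correct and F never is).
#'
#' @param h a [hierarchy()].
#' @return data.frame of 9 rows with `item_hi`, `item_lo`, `correct`,
#'   `pair_class` in premise / inference_deg1 / inference_deg2 / anchor.
#' @export
build_late_test_pairs <- function(h) {
  stopifnot(inherits(h, "hierarchy"))
  it <- h$items
  prem <- build_premise_pairs(h)
  inf <- data.frame(
    item_hi = c(it[2], it[3], it[2]),
    item_lo = c(it[4], it[5], it[5]),
    correct = c(it[2], it[3], it[2]),
    pair_class = c("inference_deg1", "inference_deg1", "inference_deg2"),
    stringsAsFactors = FALSE)
  anc <- data.frame(item_hi = it[1], item_lo = it[6], correct = it[1],
                    pair_class = "anchor", stringsAsFactors = FALSE)
  rbind(prem, inf, anc)
}

# order rows so consecutive trials share no item: greedy random draw with
# restarts (a plain rejection shuffle succeeds too rarely for 5-pair sets)
shuffle_no_shared_item <- function(trials, max_tries = 200) {
  n <- nrow(trials)
  for (k in seq_len(max_tries)) {
    remaining <- seq_len(n)
    ord <- integer(0)
    prev <- character(0)
    ok <- TRUE
    while (length(remaining)) {
      valid <- remaining[!(trials$item_hi[remaining] %in% prev |
                             trials$item_lo[remaining] %in% prev)]
      if (!length(valid)) { ok <- FALSE; break }
      pick <- if (length(valid) == 1) valid else sample(valid, 1)
      ord <- c(ord, pick)
      remaining <- setdiff(remaining, pick)
      prev <- c(trials$item_hi[pick], trials$item_lo[pick])
    }
    if (ok) return(trials[ord, , drop = FALSE])
  }
  stop("could not satisfy the no-shared-item constraint after ", max_tries,
       " attempts")
}

#' Schedule one 30-trial learning block
#'
#' Each block presents the 5 premise pairs of each hierarchy twice (once per
#' top/bottom orientation), 10 trials per hierarchy, hierarchies as
#' contiguous sub-blocks in the given category order. Within a sub-block,
#' consecutive pairs never share an item (so A>B is never followed by B>C),
#' which keeps the hierarchy order hidden.
#'
#' @param hierarchies list of 3 [hierarchy()] objects.
#' @param category_order integer permutation of 1:3 giving sub-block order
#'   (counterbalancing input).
#' @param seed optional RNG seed.
#' @return data.frame of 30 trials with columns `hierarchy`, `condition`,
#'   `item_hi`, `item_lo`, `correct`, `top_item`, `pair_class`, `phase`,
#'   `feedback`.
#' @export
schedule_learning_block <- function(hierarchies, category_order = 1:3,
                                    seed = NULL) {
  if (length(hierarchies) != 3) stop("need exactly 3 hierarchies")
  if (!identical(sort(category_order), 1:3))
    stop("category_order must be a permutation of 1:3")
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(hierarchies[category_order], function(h) {
    prem <- build_premise_pairs(h)
    # each pair twice, orientations counterbalanced
    tt <- rbind(cbind(prem, top_item = prem$item_hi),
                cbind(prem, top_item = prem$item_lo))
    tt <- shuffle_no_shared_item(tt)
    tt$hierarchy <- h$category
    tt$condition <- h$condition
    tt
  })
  out <- do.call(rbind, blocks)
  out$phase <- "learning"
  out$feedback <- TRUE
  rownames(out) <- NULL
  out[, c("hierarchy", "condition", "item_hi", "item_lo", "correct",
          "top_item", "pair_class", "phase", "feedback")]
}

#' Initialise learning exit-criterion state
#'
#' @param hierarchy_names character vector naming the hierarchies.
#' @param criterion accuracy criterion in percent (met when strictly above).
#' @param strict if FALSE, "at or above" instead of "strictly above".
#' @param min_blocks evaluation starts once this many blocks are complete.
#' @param max_blocks hard stop.
#' @param window_from_start if TRUE (default) the last-3-blocks window counts
#'   all blocks from block 1; if FALSE only blocks >= `min_blocks` enter the
#'   window.
#' @return object of class `exit_state`.
#' @export
new_exit_state <- function(hierarchy_names, criterion = 66, strict = TRUE,
                           min_blocks = 3, max_blocks = 10,
                           window_from_start = TRUE) {
  structure(list(
    history = stats::setNames(rep(list(numeric(0)), length(hierarchy_names)),
                              hierarchy_names),
    feedback_on = stats::setNames(rep(TRUE, length(hierarchy_names)),
                                  hierarchy_names),
    blocks_completed = 0L, criterion = criterion, strict = strict,
    min_blocks = min_blocks, max_blocks = max_blocks,
    window_from_start = window_from_start, finished = FALSE),
    class = "exit_state")
}

#' Update the exit criterion after a learning block
#'
#' Records each hierarchy's middle-pair (B-C, C-D, D-E) accuracy for the
#' completed block and turns feedback off for a hierarchy once its accuracy
#' exceeded the criterion in at least 2 of the last 3 recorded blocks, with
#' evaluation starting only after the minimum number of blocks. Feedback
#' never turns back on. Training finishes when all hierarchies reached
#' criterion or at the hard block cap.
#'
#' @param state an [new_exit_state()] object.
#' @param block_accuracies named numeric vector (percent, 0-100), one entry
#'   per hierarchy, middle pairs only.
#' @return updated `exit_state`.
#' @export
update_exit_criterion <- function(state, block_accuracies) {
  stopifnot(inherits(state, "exit_state"))
  if (!setequal(names(block_accuracies), names(state$history)))
    stop("block_accuracies must name every hierarchy")
  if (any(block_accuracies < 0 | block_accuracies > 100))
    stop("accuracies must be in [0, 100]")
  if (state$finished) stop("training already finished")
  state$blocks_completed <- state$blocks_completed + 1L
  for (h in names(state$history)) {
    state$history[[h]] <- c(state$history[[h]], block_accuracies[[h]])
    if (!state$feedback_on[[h]]) next
    if (state$blocks_completed < state$min_blocks) next
    hist <- state$history[[h]]
    if (!state$window_from_start)
      hist <- hist[seq(state$min_blocks, length(hist))]
    last3 <- utils::tail(hist, 3)
    hit <- if (state$strict) last3 > state$criterion else last3 >= state$criterion
    if (sum(hit) >= 2) state$feedback_on[[h]] <- FALSE
  }
  if (all(!state$feedback_on) || state$blocks_completed >= state$max_blocks)
    state$finished <- TRUE
  state
}

#' Build a sound-image association test
#'
#' Two blocks; within each block every experimental sound of every hierarchy
#' is probed three times. Each trial shows the target image plus two
#' distractors, at least one of which is a lure from the same category;
#' screen positions are randomised.
#'
#' @param hierarchies list of 3 [hierarchy()] objects.
#' @param seed optional RNG seed.
#' @return data.frame with columns `block`, `trial`, `sound`, `category`,
#'   `target`, `distractor1`, `distractor2`, `position` (1-3, target slot).
#' @export
build_sound_image_test <- function(hierarchies, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  items <- do.call(rbind, lapply(hierarchies, function(h) {
    if (length(h$items) < 3) stop("category with <3 items")
    # qualify item ids by category: the same rank letters recur across
    # hierarchies but denote different images
    data.frame(category = h$category,
               item = paste(h$category, h$items, sep = ":"),
               sound = h$experimental_sounds, stringsAsFactors = FALSE)
  }))
  out <- list()
  for (b in 1:2) {
    probes <- items[rep(seq_len(nrow(items)), times = 3), ]
    probes <- probes[sample.int(nrow(probes)), ]
    for (i in seq_len(nrow(probes))) {
      tgt <- probes$item[i]; cat_i <- probes$category[i]
      same <- setdiff(items$item[items$category == cat_i], tgt)
      d1 <- sample(same, 1)
      d2 <- sample(setdiff(items$item, c(tgt, d1)), 1)
      out[[length(out) + 1]] <- data.frame(
        block = b, trial = i, sound = probes$sound[i], category = cat_i,
        target = tgt, distractor1 = d1, distractor2 = d2,
        position = sample.int(3, 1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Score a behavioural response table
#'
#' Aggregates per-trial correctness into accuracy (percent) per subject x
#' condition x session x pair class, with cell counts. Cells with no trials
#' are reported as NA, never 0. Premise and inference (deg1 + deg2) roll-ups
#' are appended as extra pair classes.
#'
#' @param responses data.frame with columns `subject`, `condition`,
#'   `session`, `pair_class` (premise / deg1 / deg2 / anchor, or the
#'   inference_deg* spellings), `correct` (0/1).
#' @return data.frame with `subject`, `condition`, `session`, `pair_class`,
#'   `n`, `accuracy` (percent, NA when empty).
#' @export
score_behaviour <- function(responses) {
  need <- c("subject", "condition", "session", "pair_class", "correct")
  if (!all(need %in% names(responses)))
    stop("responses needs columns ", paste(need, collapse = ", "))
  pc <- responses$pair_class
  pc[pc == "inference_deg1"] <- "deg1"
  pc[pc == "inference_deg2"] <- "deg2"
  known <- c("premise", "deg1", "deg2", "anchor")
  if (!all(pc %in% known))
    stop("unknown pair_class: ", paste(setdiff(pc, known), collapse = ", "))
  responses$pair_class <- pc
  agg <- function(df, label) {
    s <- stats::aggregate(correct ~ subject + condition + session, df,
                          FUN = function(x) c(n = length(x), acc = 100 * mean(x)))
    data.frame(subject = s$subject, condition = s$condition,
               session = s$session, pair_class = label,
               n = s$correct[, "n"], accuracy = s$correct[, "acc"],
               stringsAsFactors = FALSE)
  }
  parts <- lapply(known, function(k) {
    df <- responses[responses$pair_class == k, ]
    if (nrow(df) == 0) return(NULL)
    agg(df, k)
  })
  inf <- responses[responses$pair_class %in% c("deg1", "deg2"), ]
  if (nrow(inf)) parts <- c(parts, list(agg(inf, "inference")))
  out <- do.call(rbind, parts)
  # complete the grid with NA cells
  grid <- expand.grid(subject = unique(responses$subject),
                      condition = unique(responses$condition),
                      session = unique(responses$session),
                      pair_class = unique(out$pair_class),
                      stringsAsFactors = FALSE)
  out <- merge(grid, out, all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  out[order(out$subject, out$condition, out$session, out$pair_class), ]
}
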