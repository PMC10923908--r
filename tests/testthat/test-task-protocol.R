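test_that("premise pairs are the five adjacent pairs in hierarchy order", {
  h <- hierarchy("Up", "faces")
  pp <- build_premise_pairs(h)
  expect_equal(pp$item_hi, c("A", "B", "C", "D", "E"))
  expect_equal(pp$item_lo, c("B", "C", "D", "E", "F"))
  expect_equal(pp$correct, pp$item_hi)
  # pairs follow the given order, not lexical order
  h2 <- hierarchy("Up", "faces", items = rev(LETTERS[1:6]))
  pp2 <- build_premise_pairs(h2)
  expect_equal(pp2$item_hi, c("F", "E", "D", "C", "B"))
  expect_error(hierarchy("Up", "faces", items = LETTERS[1:5]), "6 unique")
})

test_that("degree of separation counts intervening items", {
  h <- hierarchy("Control", "objects")
  expect_equal(degree_of_separation(c("B", "D"), h), 1L)
  expect_equal(degree_of_separation(c("B", "E"), h), 2L)
  expect_equal(degree_of_separation(c("A", "B"), h), 0L)
  expect_error(degree_of_separation(c("A", "Z"), h), "not in the hierarchy")
})

test_that("late test has 9 pairs with the forced class counts", {
  h <- hierarchy("Down", "scenes")
  lt <- build_late_test_pairs(h)
  expect_equal(nrow(lt), 9)
  expect_equal(as.integer(table(lt$pair_class)[c("premise", "inference_deg1",
                                                 "inference_deg2", "anchor")]),
               c(5L, 2L, 1L, 1L))
  inf <- lt[startsWith(lt$pair_class, "inference"), ]
  expect_setequal(paste(inf$item_hi, inf$item_lo),
                  c("B D", "C E", "B E"))
  anc <- lt[lt$pair_class == "anchor", ]
  expect_equal(c(anc$item_hi, anc$item_lo, anc$correct), c("A", "F", "A"))
  # premise subset is identical to build_premise_pairs
  expect_equal(lt[lt$pair_class == "premise", c("item_hi", "item_lo")],
               build_premise_pairs(h)[, c("item_hi", "item_lo")])
})

test_that("learning blocks satisfy the design constraints for many seeds", {
  hs <- make_hierarchies()
  for (seed in 1:20) {
    bl <- schedule_learning_block(hs, category_order = sample(1:3), seed = seed)
    expect_equal(nrow(bl), 30)
    # each pair appears exactly twice with both orientations
    for (h in hs) {
      sub <- bl[bl$condition == h$condition, ]
      expect_equal(nrow(sub), 10)
      key <- paste(sub$item_hi, sub$item_lo)
      expect_true(all(table(key) == 2))
      expect_true(all(tapply(sub$top_item == sub$item_hi, key, sum) == 1))
      # no consecutive trials share an item within the sub-block
      for (i in seq_len(nrow(sub) - 1)) {
        expect_length(intersect(c(sub$item_hi[i], sub$item_lo[i]),
                                c(sub$item_hi[i + 1], sub$item_lo[i + 1])),
                      0)
      }
    }
  }
})

test_that("exit criterion follows the 2-of-last-3 rule above 66%", {
  st <- new_exit_state("faces")
  st <- update_exit_criterion(st, c(faces = 70))
  st <- update_exit_criterion(st, c(faces = 70))
  expect_true(st$feedback_on[["faces"]]) # evaluation starts at block 3
  st <- update_exit_criterion(st, c(faces = 70))
  expect_false(st$feedback_on[["faces"]])
  expect_true(st$finished)

  st2 <- new_exit_state("faces")
  for (a in c(70, 60, 60)) st2 <- update_exit_criterion(st2, c(faces = a))
  expect_true(st2$feedback_on[["faces"]]) # only 1 of last 3 above criterion

  # strictly "over 66": three blocks at exactly 66 do not qualify
  st3 <- new_exit_state("faces")
  for (a in c(66, 66, 66)) st3 <- update_exit_criterion(st3, c(faces = a))
  expect_true(st3$feedback_on[["faces"]])
})

test_that("a never-learning agent stops at the 10-block cap", {
  st <- new_exit_state(c("faces", "scenes", "objects"))
  n <- 0
  while (!st$finished) {
    st <- update_exit_criterion(st, c(faces = 50, scenes = 50, objects = 50))
    n <- n + 1
  }
  expect_equal(n, 10)
  expect_true(all(st$feedback_on))
  expect_error(update_exit_criterion(st, c(faces = 50, scenes = 50,
                                           objects = 50)),
               "finished")
  expect_error(update_exit_criterion(new_exit_state("faces"),
                                     c(faces = 101)), "0, 100")
})

test_that("sound-image test satisfies the lure and repetition structure", {
  hs <- make_hierarchies()
  tr <- build_sound_image_test(hs, seed = 7)
  cat_of <- function(id) sub(":.*$", "", id) # ids are "category:item"
  for (i in seq_len(nrow(tr))) {
    dcats <- cat_of(c(tr$distractor1[i], tr$distractor2[i]))
    expect_true(tr$category[i] %in% dcats) # >=1 same-category lure
    expect_false(tr$target[i] %in% c(tr$distractor1[i], tr$distractor2[i]))
  }
  expect_equal(sort(unique(tr$block)), 1:2)
  for (b in 1:2)
    expect_true(all(table(tr$sound[tr$block == b]) == 3))
  expect_identical(build_sound_image_test(hs, seed = 7), tr)
})

test_that("behaviour scoring computes cell accuracies and roll-ups", {
  resp <- data.frame(subject = 1, condition = "Up", session = 2,
                     pair_class = rep(c("premise", "deg1"), each = 4),
                     correct = c(1, 1, 1, 1, 1, 0, 1, 0))
  sc <- score_behaviour(resp)
  expect_equal(sc$accuracy[sc$pair_class == "premise"], 100)
  expect_equal(sc$accuracy[sc$pair_class == "deg1"], 50)
  expect_equal(sc$accuracy[sc$pair_class == "inference"], 50)
  expect_error(score_behaviour(transform(resp, pair_class = "weird")),
               "unknown pair_class")
})

test_that("empty cells are reported as missing, never zero", {
  resp <- data.frame(subject = c(1, 2), condition = "Up",
                     session = c(2, 3), pair_class = "deg2",
                     correct = c(1, 0))
  sc <- score_behaviour(resp)
  s1s3 <- sc[sc$subject == 1 & sc$session == 3, ]
  expect_true(all(is.na(s1s3$accuracy)))
  expect_true(all(s1s3$n == 0))
})

test_that("scoring round-trips the behavioural generator within MC error", {
  ta <- data.frame(condition = c("Up", "Down"), session = 2,
                   pair_class = "deg2", p = c(0.75, 0.5))
  cfg <- behaviour_sim_config(40, ta, subject_effect_sd = 0.2,
                              trials_per_cell = 20, seed = 12)
  sc <- score_behaviour(generate_behaviour(cfg))
  m <- tapply(sc$accuracy[sc$pair_class == "deg2"],
              sc$condition[sc$pair_class == "deg2"], mean)
  expect_lt(abs(m[["Up"]] - 75), 6)
  expect_lt(abs(m[["Down"]] - 50), 6)
})
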