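test_that("vocabulary capping keeps the most frequent forms with lexicographic ties", {
  corp <- c("a a a a a b b b c")
  v <- build_vocab(corp, cap = 10)
  expect_length(v$forms, 3)
  v2 <- build_vocab(corp, cap = 2)
  expect_identical(v2$forms, c("a", "b"))
  # tie at the cap boundary: b and d both occur twice; b retained
  v3 <- build_vocab(c("a a a d d b b"), cap = 2)
  expect_identical(v3$forms, c("a", "b"))
  expect_error(build_vocab(character(0), 5), "empty corpus")
  expect_error(train_lm(c("a b"), alpha = 0), "alpha")
})

test_that("additive smoothing matches the closed-form Laplace estimate", {
  # counts(a -> b) = 2, total(a) = 2, |V| = 4 incl. OOV: P = (2+1)/(2+4)
  corp <- c("a b", "a b", "c")
  lm <- train_lm(corp, "bigram", alpha = 1)
  expect_length(lm_next_dist(lm, "a"), 4)
  expect_equal(lm_prob(lm, "a", "b"), 0.5, tolerance = 1e-12)
  rec <- surprisal_at(lm, c("a", "b"), position = 1)
  expect_equal(rec$surprisal, -log(0.5), tolerance = 1e-12)
  # equal observed continuations with vanishing smoothing: P -> 0.5 each
  lm2 <- train_lm(c("a b", "a c"), "bigram", alpha = 1e-9)
  expect_equal(lm_prob(lm2, "a", "b"), 0.5, tolerance = 1e-6)
  expect_equal(lm_prob(lm2, "a", "c"), 0.5, tolerance = 1e-6)
})

test_that("uniform and deterministic continuations give ln|V| and ~0 surprisal", {
  # 7 distinct forms + OOV = 8-way support; an unseen context is uniform
  corp <- c("w1 w2 w3 w4 w5 w6 w7")
  lm <- train_lm(corp, "bigram", alpha = 1)
  expect_equal(lm_prob(lm, "w7", "w1"), 1 / 8, tolerance = 1e-12)
  expect_equal(surprisal_at(lm, c("w7", "w1"), 1)$surprisal, log(8),
               tolerance = 1e-12)
  # a single repeated sentence with tiny smoothing: attested transitions
  # approach certainty
  lm3 <- train_lm(rep("x y", 50), "bigram", alpha = 1e-10)
  expect_equal(surprisal_at(lm3, c("x", "y"), 1)$surprisal, 0,
               tolerance = 1e-7)
})

test_that("next-word distributions normalize over random contexts", {
  spec <- default_language_spec("german_like")
  corp <- generate_corpus(spec, 150, seed = 2)
  forms <- unique(unlist(lapply(corp, `[[`, "tokens")))
  for (kind in c("unigram", "bigram", "trigram")) {
    lm <- train_lm(corp, kind, alpha = 0.5)
    set.seed(7)
    for (i in seq_len(34)) {
      ctx <- sample(forms, sample(0:2, 1))
      expect_equal(sum(lm_next_dist(lm, ctx)), 1, tolerance = 1e-9)
    }
  }
  lmi <- train_lm(corp, "trigram", smoothing = "interpolated", alpha = 0.5)
  expect_equal(sum(lm_next_dist(lmi, forms[1:2])), 1, tolerance = 1e-9)
})

test_that("count-based surprisals equal the brute-force oracle (5-sentence fixture)", {
  corp <- fixture_corpus()
  sents <- strsplit(corp, " ", fixed = TRUE)
  support <- c(sort(unique(unlist(sents))), "<oov>")
  for (cfg in list(list(kind = "unigram", o = 1), list(kind = "bigram", o = 2),
                   list(kind = "trigram", o = 3))) {
    lm <- train_lm(corp, cfg$kind, alpha = 0.7)
    for (s in sents) {
      total <- 0
      for (i in seq_along(s)) {
        got <- surprisal_at(lm, s, position = i - 1L)$surprisal
        want <- oracle_surprisal(sents, s, i, cfg$o, 0.7, support)
        expect_equal(got, want, tolerance = 1e-12)
        total <- total + got
      }
      # chain rule: summed surprisal equals -log joint probability
      joint <- prod(vapply(seq_along(s), function(i) {
        oracle_ngram_prob(sents, if (i == 1) character(0) else
          s[seq_len(i - 1)], s[i], cfg$o, 0.7, support)
      }, 0))
      expect_equal(total, -log(joint), tolerance = 1e-10)
    }
  }
})

test_that("unigram sentence-average surprisal is permutation invariant", {
  corp <- fixture_corpus()
  lm <- train_lm(corp, "unigram", alpha = 1)
  s <- strsplit(corp[1], " ")[[1]]
  base <- sentence_mean_surprisal(lm, s)
  set.seed(3)
  for (i in 1:10) {
    expect_identical(sentence_mean_surprisal(lm, sample(s)), base)
  }
})

test_that("mask-and-truncate mode coincides with incremental mode for count models", {
  corp <- fixture_corpus()
  lm <- train_lm(corp, "trigram", alpha = 0.5)
  s <- strsplit(corp[2], " ")[[1]]
  inc <- surprisal_at(lm, s, 2, mode = "incremental")
  mt <- surprisal_at(lm, s, 2, mode = "mask_truncate")
  expect_equal(inc$surprisal, mt$surprisal)
  expect_identical(mt$mode, "mask_truncate")
})

test_that("OOV targets raise and OOV filtering is item-wise up to the critical word", {
  corp <- fixture_corpus()
  lm <- train_lm(corp, "bigram", alpha = 1, cap = 3)
  oov_form <- setdiff(unique(unlist(strsplit(corp, " "))), lm$vocab$forms)[1]
  expect_error(surprisal_at(lm, c("n1", oov_form), 1), "out of vocabulary")

  spec <- default_language_spec("hindi_like")
  stim <- generate_stimuli(spec, "hindi_like", n_items = 10, seed = 5)
  all_tokens <- unique(unlist(lapply(stim$items$sentence, `[[`, "tokens")))
  # full coverage: identity
  v_all <- build_vocab(paste(all_tokens, collapse = " "), cap = 10000)
  expect_equal(nrow(filter_oov(stim, v_all)$items), 40)
  # drop forms occurring only after the critical region (afterthought NP):
  # items are retained because the exclusion window ends at the critical word
  post_critical <- unique(unlist(lapply(stim$items$sentence, function(s) {
    s$tokens[-seq_len(s$critical_index + 1L)]
  })))
  pre_critical <- unique(unlist(lapply(stim$items$sentence, function(s) {
    s$tokens[seq_len(s$critical_index + 1L)]
  })))
  only_post <- setdiff(post_critical, pre_critical)
  v_post <- v_all
  v_post$forms <- setdiff(v_post$forms, only_post)
  expect_equal(nrow(filter_oov(stim, v_post)$items), 40)
  # drop the initial-NP lemma of 3 items: those items vanish from all cells
  drop_items <- unique(stim$items$item_id)[1:3]
  drop_forms <- unique(unlist(lapply(
    stim$items$sentence[stim$items$item_id %in% drop_items],
    function(s) s$tokens[1])))
  v_cut <- v_all
  v_cut$forms <- setdiff(v_cut$forms, drop_forms)
  flt <- filter_oov(stim, v_cut)
  expect_equal(sort(unique(flt$items$item_id)),
               sort(setdiff(unique(stim$items$item_id), drop_items)))
  expect_true(all(table(flt$items$item_id) == 4))
})

test_that("language models round-trip through JSON serialization", {
  corp <- fixture_corpus()
  lm <- train_lm(corp, "trigram", alpha = 0.3, model_id = "fx")
  tmp <- tempfile(fileext = ".json")
  write_lm(lm, tmp)
  back <- read_lm(tmp)
  s <- strsplit(corp[3], " ")[[1]]
  for (i in seq_along(s)) {
    expect_equal(surprisal_at(back, s, i - 1L)$surprisal,
                 surprisal_at(lm, s, i - 1L)$surprisal, tolerance = 1e-12)
  }
  expect_identical(back$model_id, "fx")
})
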