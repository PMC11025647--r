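test_that("language_spec validates probabilities, distribution and lexicon", {
  expect_error(language_spec(p_mark_agent = 1.2), "probabilities")
  expect_error(language_spec(word_order_dist = c("A-P-V" = 0.5)),
               "summing to 1")
  expect_error(language_spec(word_order_dist = c("A-P-V" = 1),
                             grammatical_orders = "P-A-V"),
               "subset")
  expect_error(language_spec(lexicon_sizes = c(nouns = 0)), "lexicon_sizes")
  spec <- default_language_spec("basque_like")
  expect_s3_class(spec, "language_spec")
  expect_equal(sum(spec$word_order_dist), 1)
})

test_that("corpus generation follows the word-order distribution", {
  rigid <- language_spec(word_order_dist = c("A-P-V" = 1))
  corp <- generate_corpus(rigid, 25, seed = 3)
  expect_true(all(vapply(corp, function(s) s$template, "") == "A-P-V"))
  expect_true(all(vapply(corp, function(s) s$grammatical, TRUE)))
  # determinism: same spec and seed twice gives identical token sequences
  expect_identical(generate_corpus(rigid, 25, seed = 3), corp)
  # empirical template frequencies match the distribution (n = 10000)
  spec <- language_spec(word_order_dist = c("A-P-V" = 0.7, "P-A-V" = 0.3))
  corp <- generate_corpus(spec, 10000, seed = 11)
  freq <- table(vapply(corp, function(s) s$template, "")) / 10000
  expect_lt(abs(freq[["A-P-V"]] - 0.7), 0.02)
  expect_lt(abs(freq[["P-A-V"]] - 0.3), 0.02)
})

test_that("corpus sentences have a well-formed critical region", {
  spec <- default_language_spec("german_like")
  corp <- generate_corpus(spec, 50, seed = 5)
  for (s in corp) {
    expect_gte(s$critical_index, 0)
    expect_lt(s$critical_index, length(s$tokens))
    expect_true(s$role_tags[s$critical_index + 1L] %in% c("verb", "aux"))
  }
})

test_that("stimulus sets are balanced 2x2 factorials", {
  spec <- default_language_spec("german_like")
  stim <- generate_stimuli(spec, "german_like", n_items = 8, seed = 2)
  expect_equal(nrow(stim$items), 32)
  cells <- table(stim$items$cond1, stim$items$cond2)
  expect_true(all(cells == 8))
  # every item appears exactly once per cell
  expect_true(all(table(stim$items$item_id) == 4))
  # reanalysis flag equals the coding rule output
  expect_equal(stim$items$reanalysis,
               as.integer(code_agent_preference("german_like",
                                                stim$items$cond1,
                                                stim$items$cond2) ==
                            "reanalysis"))
})

test_that("hindi-like items are patient-disambiguating at the verb", {
  spec <- default_language_spec("hindi_like")
  stim <- generate_stimuli(spec, "hindi_like", n_items = 6, seed = 4)
  for (s in stim$items$sentence) {
    expect_identical(s$role_tags[1], "patient")
    expect_identical(s$role_tags[s$critical_index + 1L], "verb")
  }
})

test_that("basque-like syncretism: ambiguous forms identical, unambiguous differ", {
  spec <- default_language_spec("basque_like")
  stim <- generate_stimuli(spec, "basque_like", n_items = 4, seed = 9)
  it <- stim$items
  for (id in unique(it$item_id)) {
    np <- function(c1, c2) {
      s <- it$sentence[it$item_id == id & it$cond1 == c1 & it$cond2 == c2]
      s[[1]]$tokens[1]
    }
    expect_identical(np("agent", "ambiguous"), np("patient", "ambiguous"))
    expect_false(identical(np("agent", "unambiguous"),
                           np("patient", "unambiguous")))
  }
})

test_that("agent preference coding reproduces the canonical condition table", {
  rows <- list(
    list("german_like", "agent-initial", "accusative", "no_reanalysis"),
    list("german_like", "patient-initial", "accusative", "reanalysis"),
    list("german_like", "agent-initial", "dative", "no_reanalysis"),
    list("german_like", "patient-initial", "dative", "reanalysis"),
    list("hindi_like", "ambiguous", "imperfective", "reanalysis"),
    list("hindi_like", "unambiguous", "imperfective", "no_reanalysis"),
    list("hindi_like", "ambiguous", "perfective", "reanalysis"),
    list("hindi_like", "unambiguous", "perfective", "no_reanalysis"),
    list("basque_like", "patient", "ambiguous", "reanalysis"),
    list("basque_like", "agent", "ambiguous", "no_reanalysis"),
    list("basque_like", "patient", "unambiguous", "no_reanalysis"),
    list("basque_like", "agent", "unambiguous", "no_reanalysis"))
  for (r in rows) {
    expect_identical(code_agent_preference(r[[1]], r[[2]], r[[3]]), r[[4]])
  }
  expect_error(code_agent_preference("german_like", "ambiguous", "dative"),
               "unknown label")
  expect_error(generate_stimuli(default_language_spec("german_like"),
                                "swahili_like", 4), "arg")
})

test_that("ungrammatical permutations avoid all grammatical templates", {
  spec <- language_spec(word_order_dist = c("A-P-V" = 0.7, "P-A-V" = 0.3))
  corp <- generate_corpus(spec, 10, seed = 6)
  for (s in corp) {
    vars <- permute_ungrammatical(s, spec, k = 4, seed = 8)
    # brute force: 3 constituents have 6 orders, 2 grammatical, 1 original
    expect_lte(length(vars), 4)
    for (v in vars) {
      expect_false(v$template %in% spec$grammatical_orders)
      expect_false(v$grammatical)
      expect_false(identical(v$tokens, s$tokens))
      # critical index follows the verb to its new position
      expect_identical(v$tokens[v$critical_index + 1L],
                       s$tokens[s$critical_index + 1L])
    }
    # determinism
    expect_identical(permute_ungrammatical(s, spec, k = 4, seed = 8), vars)
  }
})

test_that("permutation of a fully grammatical order space warns and returns empty", {
  spec <- language_spec(word_order_dist = c("A-V" = 0.5, "P-V" = 0.5),
                        grammatical_orders = c("A-V", "P-V"))
  s <- generate_corpus(spec, 1, seed = 1)[[1]]
  # a 2-token sentence whose only reordering is... possibly grammatical;
  # V-A / V-P orders are ungrammatical here, so force both templates in
  spec_all <- language_spec(
    word_order_dist = c("A-V" = 0.25, "P-V" = 0.25, "V-A" = 0.25,
                        "V-P" = 0.25),
    grammatical_orders = c("A-V", "P-V", "V-A", "V-P"))
  expect_warning(out <- permute_ungrammatical(s, spec_all, k = 2, seed = 1),
                 "only 0 ungrammatical")
  expect_length(out, 0)
})

test_that("specs, corpora and stimulus tables round-trip through files", {
  spec <- default_language_spec("hindi_like")
  tmp_yaml <- tempfile(fileext = ".yaml")
  tmp_json <- tempfile(fileext = ".json")
  write_language_spec(spec, tmp_yaml)
  write_language_spec(spec, tmp_json)
  for (path in c(tmp_yaml, tmp_json)) {
    back <- read_language_spec(path)
    expect_equal(back$alignment, spec$alignment)
    expect_equal(back$word_order_dist, spec$word_order_dist)
    expect_equal(back$lexicon_sizes, spec$lexicon_sizes)
  }
  corp <- generate_corpus(spec, 10, seed = 2)
  tmp <- tempfile(fileext = ".txt")
  write_corpus(corp, tmp)
  lines <- read_corpus(tmp)
  expect_length(lines, 10)
  expect_identical(strsplit(lines[1], " ")[[1]], corp[[1]]$tokens)
  stim <- generate_stimuli(spec, "hindi_like", 3, seed = 2)
  tmp2 <- tempfile(fileext = ".tsv")
  write_stimuli(stim, tmp2)
  tab <- read_stimuli(tmp2)
  expect_equal(nrow(tab), 12)
  expect_named(tab, c("item_id", "cond1", "cond2", "reanalysis",
                      "critical_index", "tokens", "role_tags"))
})
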