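# Shared fixtures and independent oracles used across test files.

# A fixed 5-sentence fixture corpus (space-separated token strings).
fixture_corpus <- function() {
  c("n1 n2-acc v1.acc aux1.ag",
    "n3 n1-acc v1.acc aux2.pt",
    "n2 n3-dat v2.dat aux1.ag",
    "n1 n2-acc v2.dat aux1.pt",
    "n2 v1.acc aux1.ag")
}

# Brute-force count-and-divide n-gram conditional probability with
# additive smoothing, written independently of the package internals.
# `sents` is a list of token vectors already mapped to the vocabulary;
# `support` is the event space (vocabulary forms plus the OOV symbol).
oracle_ngram_prob <- function(sents, context, target, order, alpha,
                              support) {
  bos <- "<s>"
  ctx <- utils::tail(c(rep(bos, order - 1L), context), order - 1L)
  num <- 0
  den <- 0
  for (s in sents) {
    padded <- c(rep(bos, order - 1L), s)
    for (i in seq_along(s)) {
      this_ctx <- padded[seq(i, length.out = order - 1L)]
      if (identical(this_ctx, ctx)) {
        den <- den + 1
        if (s[i] == target) num <- num + 1
      }
    }
  }
  (num + alpha) / (den + alpha * length(support))
}

# Oracle surprisal of token at 1-based position `i` of `tokens`.
oracle_surprisal <- function(sents, tokens, i, order, alpha, support) {
  ctx <- if (i == 1L) character(0) else tokens[seq_len(i - 1L)]
  -log(oracle_ngram_prob(sents, ctx, tokens[i], order, alpha, support))
}

# Small synthetic ERP dataset with one stimulus per item and known
# generative config; used by the GAM and stacking tests.
make_erp_data <- function(n_items = 24, n_part = 12, n_el = 16, seed = 1,
                          config = NULL) {
  set.seed(seed)
  stim <- data.frame(stim_id = sprintf("s%03d", seq_len(n_items)),
                     item_id = sprintf("i%03d", seq_len(n_items)),
                     cond = rep(c(0, 1), length.out = n_items),
                     surp = stats::rnorm(n_items, 3, 1))
  if (is.null(config)) {
    config <- erp_gen_config(n_participants = n_part, seed = seed)
  }
  generate_erp(stim, make_layout(n_el), config)
}

# A null-effect generator config (no condition or surprisal field).
null_erp_config <- function(n_part = 12, seed = 1, sd_noise = 2) {
  erp_gen_config(
    field_cond = spatial_field(c(0, 0), widths = 0.5, amplitudes = 0),
    field_surp = spatial_field(c(0, 0), widths = 0.5, amplitudes = 0),
    sd_noise = sd_noise, n_participants = n_part, seed = seed)
}
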