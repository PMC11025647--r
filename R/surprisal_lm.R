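#' Build a frequency-capped vocabulary from a corpus
#'
#' Retains the `cap` most frequent word forms; all other forms map to
#' the reserved out-of-vocabulary (OOV) symbol. Ties at the cap
#' boundary are broken lexicographically (smaller form retained).
#'
#' @param corpus a list of `n400_sentence` objects, or a character
#'   vector of space-separated token strings.
#' @param cap maximum vocabulary size (OOV symbol not counted).
#' @return an object of class `lm_vocabulary` with fields `forms`
#'   (ordered by descending frequency), `cap` and `oov_symbol`.
#' @export
build_vocab <- function(corpus, cap = 50000L) {
  stopifnot(cap >= 1)
  toks <- unlist(corpus_tokens(corpus), use.names = FALSE)
  if (!length(toks)) stop("empty corpus", call. = FALSE)
  freq <- table(toks)
  ord <- order(-as.integer(freq), names(freq))  # ties: lexicographic
  forms <- names(freq)[ord]
  forms <- forms[seq_len(min(cap, length(forms)))]
  structure(list(forms = forms, cap = as.integer(cap),
                 oov_symbol = "<oov>"),
            class = "lm_vocabulary")
}

# internal: tokens of a corpus in either representation
corpus_tokens <- function(corpus) {
  if (is.character(corpus)) return(strsplit(corpus, " ", fixed = TRUE))
  lapply(corpus, function(s) {
    if (inherits(s, "n400_sentence")) s$tokens else as.character(s)
  })
}

# internal: map tokens onto the vocabulary (OOV symbol for the rest)
map_to_vocab <- function(tokens, vocab) {
  ifelse(tokens %in% vocab$forms, tokens, vocab$oov_symbol)
}

#' Train a count-based incremental language model
#'
#' Fits unigram, bigram or trigram conditional distributions over the
#' vocabulary (including the OOV symbol) with additive (Laplace)
#' smoothing, or an interpolated mixture of all orders up to the model
#' order. An implicit begin-of-sentence symbol conditions the first
#' word; no end-of-sentence event is scored. Training is deterministic
#' for these count-based estimators; the `seed` argument is accepted
#' for interface stability.
#'
#' @param corpus training corpus (see [build_vocab()]).
#' @param kind `"unigram"`, `"bigram"` or `"trigram"`.
#' @param smoothing `"additive"` or `"interpolated"` (an evenly weighted
#'   mixture of the additive estimates of orders `1..order` unless
#'   `lambda` is given).
#' @param alpha additive smoothing constant, strictly positive.
#' @param vocab an [build_vocab()] result, or `NULL` to build one from
#'   the corpus with cap `cap`.
#' @param cap vocabulary cap used when `vocab` is `NULL`.
#' @param lambda optional mixture weights for interpolated smoothing
#'   (length = model order, summing to 1).
#' @param model_id label attached to surprisal records.
#' @param seed unused for count-based models.
#' @return an object of class `incremental_lm`.
#' @export
train_lm <- function(corpus, kind = c("bigram", "unigram", "trigram"),
                     smoothing = c("additive", "interpolated"),
                     alpha = 1, vocab = NULL, cap = 50000L, lambda = NULL,
                     model_id = NULL, seed = 1L) {
  kind <- match.arg(kind)
  smoothing <- match.arg(smoothing)
  if (!is.numeric(alpha) || alpha <= 0) {
    stop("`alpha` must be > 0", call. = FALSE)
  }
  sents <- corpus_tokens(corpus)
  if (!length(sents)) stop("empty corpus", call. = FALSE)
  if (is.null(vocab)) vocab <- build_vocab(corpus, cap)
  order <- switch(kind, unigram = 1L, bigram = 2L, trigram = 3L)
  if (smoothing == "interpolated") {
    if (is.null(lambda)) lambda <- rep(1 / order, order)
    stopifnot(length(lambda) == order, abs(sum(lambda) - 1) < 1e-8,
              all(lambda >= 0))
  } else {
    lambda <- c(rep(0, order - 1L), 1)
  }
  bos <- "<s>"
  counts <- vector("list", order)
  for (o in seq_len(order)) {
    ctxs <- character(0)
    words <- character(0)
    for (s in sents) {
      w <- map_to_vocab(s, vocab)
      n <- length(w)
      if (!n) next
      padded <- c(rep(bos, o - 1L), w)
      ctx <- if (o == 1L) rep("<null>", n) else
        vapply(seq_len(n), function(i) {
          paste(padded[seq(i, length.out = o - 1L)], collapse = " ")
        }, "")
      ctxs <- c(ctxs, ctx)
      words <- c(words, w)
    }
    pair <- table(paste(ctxs, words, sep = "\r"))
    tot <- table(ctxs)
    counts[[o]] <- list(
      pair = stats::setNames(as.numeric(pair), names(pair)),
      total = stats::setNames(as.numeric(tot), names(tot)))
  }
  structure(list(kind = kind, order = order, smoothing = smoothing,
                 alpha = alpha, lambda = lambda, vocab = vocab,
                 counts = counts,
                 model_id = model_id %||% kind),
            class = "incremental_lm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.incremental_lm <- function(x, ...) {
  cat(sprintf("<incremental_lm %s: %s, %s smoothing (alpha=%g), |V|=%d+OOV>\n",
              x$model_id, x$kind, x$smoothing, x$alpha,
              length(x$vocab$forms)))
  invisible(x)
}

# internal: event space of the model (vocabulary forms plus OOV)
lm_support <- function(lm) {
  v <- lm$vocab
  if (v$oov_symbol %in% v$forms) v$forms else c(v$forms, v$oov_symbol)
}

#' Conditional next-word distribution of a trained model
#'
#' @param lm an `incremental_lm`.
#' @param context character vector of preceding tokens (raw forms;
#'   mapped onto the vocabulary internally). Begin-of-sentence padding
#'   is added as needed.
#' @return named numeric vector of probabilities over the vocabulary
#'   including the OOV symbol; sums to 1.
#' @export
lm_next_dist <- function(lm, context = character(0)) {
  support <- lm_support(lm)
  vsize <- length(support)
  ctx <- c(rep("<s>", lm$order - 1L), map_to_vocab(context, lm$vocab))
  p <- rep(0, vsize)
  for (o in seq_len(lm$order)) {
    if (lm$lambda[o] == 0) next
    key <- if (o == 1L) "<null>" else
      paste(utils::tail(ctx, o - 1L), collapse = " ")
    cnt <- lm$counts[[o]]
    tot <- cnt$total[key]
    if (is.na(tot)) tot <- 0
    cw <- cnt$pair[paste(key, support, sep = "\r")]
    cw[is.na(cw)] <- 0
    p <- p + lm$lambda[o] * (cw + lm$alpha) / (tot + lm$alpha * vsize)
  }
  stats::setNames(as.numeric(p), support)
}

#' Conditional probability of one word
#'
#' @inheritParams lm_next_dist
#' @param word the target form (must be in-vocabulary or the OOV
#'   symbol; other forms are mapped to OOV).
#' @return a single probability.
#' @export
lm_prob <- function(lm, context, word) {
  support <- lm_support(lm)
  vsize <- length(support)
  w <- map_to_vocab(word, lm$vocab)
  ctx <- c(rep("<s>", lm$order - 1L), map_to_vocab(context, lm$vocab))
  p <- 0
  for (o in seq_len(lm$order)) {
    if (lm$lambda[o] == 0) next
    key <- if (o == 1L) "<null>" else
      paste(utils::tail(ctx, o - 1L), collapse = " ")
    cnt <- lm$counts[[o]]
    tot <- cnt$total[key]
    if (is.na(tot)) tot <- 0
    cw <- cnt$pair[paste(key, w, sep = "\r")]
    if (is.na(cw)) cw <- 0
    p <- p + lm$lambda[o] * (cw + lm$alpha) / (tot + lm$alpha * vsize)
  }
  as.numeric(p)
}

#' Surprisal of a word in context
#'
#' Computes the surprisal, in nats, of the token at `position` given
#' its left context: `-log P(w | context)`. In `"incremental"` mode the
#' model conditions on all preceding tokens. In `"mask_truncate"` mode
#' the target slot is masked and all right context removed before
#' scoring; for the left-to-right count-based estimators provided here
#' the two modes coincide by construction (the mode is recorded so that
#' bidirectional estimators can differ).
#'
#' @param lm an `incremental_lm`.
#' @param sentence an `n400_sentence` or character vector of tokens.
#' @param position 0-based target position (defaults to the sentence's
#'   critical index when available).
#' @param mode `"incremental"` or `"mask_truncate"`.
#' @return one-row data.frame: `item_id`, `critical_word`,
#'   `surprisal` (nats), `model_id`, `mode`.
#' @export
surprisal_at <- function(lm, sentence, position = NULL,
                         mode = c("incremental", "mask_truncate")) {
  mode <- match.arg(mode)
  if (inherits(sentence, "n400_sentence")) {
    tokens <- sentence$tokens
    item_id <- sentence$item_id
    if (is.null(position)) position <- sentence$critical_index
  } else {
    tokens <- as.character(sentence)
    item_id <- NA_character_
  }
  if (is.null(position) || position < 0 || position >= length(tokens)) {
    stop("`position` must satisfy 0 <= position < sentence length",
         call. = FALSE)
  }
  target <- tokens[position + 1L]
  if (!(target %in% lm$vocab$forms)) {
    stop(sprintf("target '%s' is out of vocabulary; filter stimuli first",
                 target), call. = FALSE)
  }
  context <- if (position == 0) character(0) else tokens[seq_len(position)]
  p <- lm_prob(lm, context, target)
  data.frame(item_id = item_id, critical_word = target,
             surprisal = -log(p), model_id = lm$model_id, mode = mode,
             stringsAsFactors = FALSE)
}

#' Mean per-word surprisal of a sentence
#'
#' Averages `-log P(w_t | w_{<t})` over all token positions, scoring
#' word-by-word in linear order. Out-of-vocabulary tokens are scored as
#' the OOV symbol.
#'
#' @param lm an `incremental_lm`.
#' @param sentence an `n400_sentence` or character vector of tokens.
#' @return mean surprisal in nats.
#' @export
sentence_mean_surprisal <- function(lm, sentence) {
  tokens <- if (inherits(sentence, "n400_sentence")) sentence$tokens else
    as.character(sentence)
  n <- length(tokens)
  if (!n) stop("empty sentence", call. = FALSE)
  s <- vapply(seq_len(n), function(i) {
    ctx <- if (i == 1L) character(0) else tokens[seq_len(i - 1L)]
    -log(lm_prob(lm, ctx, tokens[i]))
  }, 0)
  mean(s)
}

#' Drop stimulus items containing out-of-vocabulary material
#'
#' Removes every item (across all four cells, preserving factorial
#' balance) for which any cell contains an out-of-vocabulary token at a
#' position up to and including the critical word. Tokens after the
#' critical index do not trigger exclusion.
#'
#' @param stimuli a `stimulus_set`.
#' @param vocab an `lm_vocabulary`.
#' @return the filtered `stimulus_set` (possibly with zero items, with
#'   a warning).
#' @export
filter_oov <- function(stimuli, vocab) {
  stopifnot(inherits(stimuli, "stimulus_set"),
            inherits(vocab, "lm_vocabulary"))
  ok_cell <- vapply(stimuli$items$sentence, function(s) {
    pre <- s$tokens[seq_len(s$critical_index + 1L)]
    all(pre %in% vocab$forms)
  }, TRUE)
  bad_items <- unique(stimuli$items$item_id[!ok_cell])
  keep <- !(stimuli$items$item_id %in% bad_items)
  out <- stimuli
  out$items <- stimuli$items[keep, , drop = FALSE]
  rownames(out$items) <- NULL
  if (!nrow(out$items)) {
    warning("all items contained OOV material before the critical word",
            call. = FALSE)
  }
  out
}

#' Critical-word surprisal for every cell of a stimulus set
#'
#' Extracts the surprisal of each item's critical word under one or
#' more trained language models.
#'
#' @param stimuli a `stimulus_set` (OOV-filtered for each model first;
#'   see [filter_oov()]).
#' @param lms a single `incremental_lm` or a list of them.
#' @param mode passed to [surprisal_at()].
#' @return data.frame with columns `item_id`, `cond1`, `cond2`,
#'   `reanalysis`, `model_id`, `mode`, `critical_word`,
#'   `surprisal_nats`.
#' @export
stimulus_surprisal <- function(stimuli, lms,
                               mode = c("incremental", "mask_truncate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (inherits(lms, "incremental_lm")) lms <- list(lms)
  out <- list()
  for (lm in lms) {
    flt <- filter_oov(stimuli, lm$vocab)
    it <- flt$items
    recs <- lapply(it$sentence, surprisal_at, lm = lm, mode = mode)
    recs <- do.call(rbind, recs)
    out[[length(out) + 1L]] <- data.frame(
      item_id = it$item_id, cond1 = it$cond1, cond2 = it$cond2,
      reanalysis = it$reanalysis, model_id = recs$model_id,
      mode = recs$mode, critical_word = recs$critical_word,
      surprisal_nats = recs$surprisal, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Serialize a count-based language model to JSON
#'
#' Stores the count tables, smoothing configuration and embedded
#' vocabulary; [read_lm()] restores an equivalent model.
#'
#' @param lm an `incremental_lm`.
#' @param path output path (`.json`).
#' @return the path, invisibly.
#' @export
write_lm <- function(lm, path) {
  stopifnot(inherits(lm, "incremental_lm"))
  x <- list(kind = lm$kind, order = lm$order, smoothing = lm$smoothing,
            alpha = lm$alpha, lambda = lm$lambda,
            model_id = lm$model_id,
            vocab = list(forms = lm$vocab$forms, cap = lm$vocab$cap,
                         oov_symbol = lm$vocab$oov_symbol),
            counts = lapply(lm$counts, function(cn) {
              list(pair_keys = names(cn$pair), pair_values = unname(cn$pair),
                   total_keys = names(cn$total),
                   total_values = unname(cn$total))
            }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lm
#' @export
read_lm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  counts <- lapply(x$counts, function(cn) {
    list(pair = stats::setNames(as.numeric(unlist(cn$pair_values)),
                                unlist(cn$pair_keys)),
         total = stats::setNames(as.numeric(unlist(cn$total_values)),
                                 unlist(cn$total_keys)))
  })
  structure(list(kind = x$kind, order = as.integer(x$order),
                 smoothing = x$smoothing, alpha = x$alpha,
                 lambda = as.numeric(unlist(x$lambda)),
                 vocab = structure(list(forms = unlist(x$vocab$forms),
                                        cap = as.integer(x$vocab$cap),
                                        oov_symbol = x$vocab$oov_symbol),
                                   class = "lm_vocabulary"),
                 counts = counts, model_id = x$model_id),
            class = "incremental_lm")
}
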