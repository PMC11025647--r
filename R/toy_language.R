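#' Generative description of a toy verb-final language
#'
#' A `language_spec` collects the structural parameters of a small
#' artificial language: its case alignment, the probabilities that agent
#' and patient noun phrases carry overt case marking, the probability
#' that a marked form is surface-syncretic (ambiguous between roles),
#' a distribution over constituent-order templates, and lexicon sizes.
#' Sentences are built from single-token constituents; case marking is
#' realized as a suffix on the noun form, and syncretism as surface-form
#' identity between the two case forms.
#'
#' Templates are hyphen-joined constituent codes drawn from
#' `A` (agent NP), `P` (patient NP), `V` (verb) and `Aux` (auxiliary),
#' e.g. `"A-P-V"` or `"P-A-V-Aux"`.
#'
#' @param alignment one of `"accusative"` (agent unmarked, patient
#'   marked), `"ergative"` (agent marked, patient unmarked) or
#'   `"split"` (agent marking conditioned on an aspect-like label).
#' @param p_mark_agent,p_mark_patient probabilities of overt case
#'   marking on agent / patient NPs.
#' @param p_syncretic probability that a marked form is surface-ambiguous.
#' @param word_order_dist named numeric vector: a discrete distribution
#'   over templates; must sum to 1.
#' @param p_agent_drop probability that the agent constituent of a
#'   transitive template is dropped (applied only when the reduced
#'   template is itself grammatical).
#' @param lexicon_sizes named integer vector with entries `nouns`,
#'   `tverbs`, `iverbs_agent`, `iverbs_patient`, `auxiliaries`,
#'   `markers`; all at least 1.
#' @param grammatical_orders character vector of templates considered
#'   grammatical; must be a subset of the support of `word_order_dist`.
#' @return an object of class `language_spec`.
#' @export
language_spec <- function(alignment = c("accusative", "ergative", "split"),
                          p_mark_agent = 0,
                          p_mark_patient = 1,
                          p_syncretic = 0.5,
                          word_order_dist = c("A-P-V" = 1),
                          p_agent_drop = 0,
                          lexicon_sizes = c(nouns = 40L, tverbs = 12L,
                                            iverbs_agent = 6L,
                                            iverbs_patient = 6L,
                                            auxiliaries = 4L, markers = 4L),
                          grammatical_orders = names(word_order_dist)) {
  alignment <- match.arg(alignment)
  probs <- c(p_mark_agent = p_mark_agent, p_mark_patient = p_mark_patient,
             p_syncretic = p_syncretic, p_agent_drop = p_agent_drop)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(word_order_dist)) || any(!nzchar(names(word_order_dist)))) {
    stop("`word_order_dist` must be a named vector of templates", call. = FALSE)
  }
  if (abs(sum(word_order_dist) - 1) > 1e-8 || any(word_order_dist < 0)) {
    stop("`word_order_dist` must be a probability distribution summing to 1",
         call. = FALSE)
  }
  if (!all(grammatical_orders %in% names(word_order_dist))) {
    stop("`grammatical_orders` must be a subset of the support of ",
         "`word_order_dist`", call. = FALSE)
  }
  need <- c("nouns", "tverbs", "iverbs_agent", "iverbs_patient",
            "auxiliaries", "markers")
  if (!all(need %in% names(lexicon_sizes)) || any(lexicon_sizes[need] < 1)) {
    stop("`lexicon_sizes` needs entries >= 1 for: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  structure(
    list(alignment = alignment,
         p_mark_agent = p_mark_agent, p_mark_patient = p_mark_patient,
         p_syncretic = p_syncretic,
         word_order_dist = word_order_dist,
         p_agent_drop = p_agent_drop,
         lexicon_sizes = as.integer(lexicon_sizes[need]),
         grammatical_orders = grammatical_orders),
    names_lexicon = need,
    class = "language_spec")
}

#' @export
print.language_spec <- function(x, ...) {
  cat("<language_spec>\n")
  cat("  alignment:", x$alignment, "\n")
  cat(sprintf("  marking: agent %.2f, patient %.2f (syncretic %.2f)\n",
              x$p_mark_agent, x$p_mark_patient, x$p_syncretic))
  cat("  word orders:",
      paste(sprintf("%s (%.2f)", names(x$word_order_dist), x$word_order_dist),
            collapse = ", "), "\n")
  cat("  grammatical:", paste(x$grammatical_orders, collapse = ", "), "\n")
  invisible(x)
}

#' Preset language specifications for the three study designs
#'
#' Returns a `language_spec` whose alignment and marking gradient mirror
#' the three experimental languages: an accusative language with rigid
#' verb-final order (unmarked patients rare), a split-alignment language
#' with aspect-conditioned agent marking (unmarked patients mixed), and
#' an ergative language (unmarked patients common).
#'
#' @param design_name one of `"german_like"`, `"hindi_like"`,
#'   `"basque_like"`.
#' @return a `language_spec`.
#' @export
default_language_spec <- function(design_name = c("german_like", "hindi_like",
                                                  "basque_like")) {
  design_name <- match.arg(design_name)
  switch(design_name,
    german_like = language_spec(
      alignment = "accusative",
      p_mark_agent = 0, p_mark_patient = 0.9, p_syncretic = 0.3,
      word_order_dist = c("A-P-V-Aux" = 0.7, "P-A-V-Aux" = 0.1,
                          "A-V-Aux" = 0.1, "P-V-Aux" = 0.1),
      grammatical_orders = c("A-P-V-Aux", "P-A-V-Aux", "A-V-Aux", "P-V-Aux")),
    hindi_like = language_spec(
      alignment = "split",
      p_mark_agent = 0.5, p_mark_patient = 0.5, p_syncretic = 0.4,
      word_order_dist = c("A-P-V" = 0.55, "P-A-V" = 0.15, "P-V-A" = 0.1,
                          "A-V" = 0.1, "P-V" = 0.1),
      grammatical_orders = c("A-P-V", "P-A-V", "P-V-A", "A-V", "P-V")),
    basque_like = language_spec(
      alignment = "ergative",
      p_mark_agent = 0.9, p_mark_patient = 0, p_syncretic = 0.4,
      word_order_dist = c("A-P-V" = 0.5, "P-A-V" = 0.2,
                          "A-V" = 0.15, "P-V" = 0.15),
      grammatical_orders = c("A-P-V", "P-A-V", "A-V", "P-V")))
}

# internal: lexicon form tables derived from a language_spec
lexicon_forms <- function(spec) {
  n <- spec$lexicon_sizes
  names(n) <- attr(spec, "names_lexicon")
  list(nouns = sprintf("n%03d", seq_len(n[["nouns"]])),
       tverbs = sprintf("v%03d", seq_len(n[["tverbs"]])),
       iverbs_agent = sprintf("va%02d", seq_len(n[["iverbs_agent"]])),
       iverbs_patient = sprintf("vp%02d", seq_len(n[["iverbs_patient"]])),
       auxiliaries = sprintf("aux%02d", seq_len(n[["auxiliaries"]])))
}

# internal: realize a noun-phrase token given role and marking decisions.
# Marked forms carry an alignment-specific case suffix; a syncretic
# marked form carries the role-neutral suffix "-x"; unmarked forms are
# bare (also role-neutral). For accusative alignment the patient suffix
# matches the verb's case class ("acc"/"dat").
realize_np <- function(noun, role, marked, syncretic, alignment,
                       vclass = "acc") {
  if (!marked) return(noun)
  if (syncretic) return(paste0(noun, "-x"))
  suffix <- if (role == "agent") {
    switch(alignment, accusative = "ag", split = "erg", ergative = "erg")
  } else {
    switch(alignment, accusative = vclass, split = "ko", ergative = "pt")
  }
  paste0(noun, "-", suffix)
}

# internal: constituent codes of a sentence from its role tags
template_of <- function(role_tags) {
  code <- c(agent = "A", patient = "P", verb = "V", aux = "Aux")
  paste(code[role_tags], collapse = "-")
}

# internal: sentence constructor (critical_index is 0-based)
new_sentence <- function(tokens, role_tags, critical_index, grammatical,
                         item_id = NA_character_) {
  stopifnot(length(tokens) == length(role_tags),
            critical_index >= 0, critical_index < length(tokens))
  structure(list(tokens = tokens, role_tags = role_tags,
                 critical_index = as.integer(critical_index),
                 grammatical = isTRUE(grammatical),
                 item_id = item_id,
                 template = template_of(role_tags)),
            class = "n400_sentence")
}

#' @export
print.n400_sentence <- function(x, ...) {
  marks <- rep(" ", length(x$tokens))
  marks[x$critical_index + 1L] <- "*"
  cat(sprintf("<sentence %s [%s]%s> %s\n",
              ifelse(is.na(x$item_id), "", x$item_id), x$template,
              if (x$grammatical) "" else " ungrammatical",
              paste0(x$tokens, marks, collapse = " ")))
  invisible(x)
}

#' Generate a grammatical toy-language corpus
#'
#' Samples `n_sentences` sentences whose constituent-order templates are
#' drawn from the spec's word-order distribution restricted to its
#' grammatical orders. Case marking, syncretism and (for split
#' alignment) aspect conditioning follow the spec's probabilities. The
#' critical index points at the auxiliary when the template has one,
#' otherwise at the verb.
#'
#' @param spec a [language_spec()].
#' @param n_sentences number of sentences, at least 1.
#' @param seed integer seed; the same spec and seed give byte-identical
#'   output.
#' @return a list of sentences (class `n400_sentence`).
#' @export
generate_corpus <- function(spec, n_sentences, seed = 1L) {
  stopifnot(inherits(spec, "language_spec"), n_sentences >= 1)
  dist <- spec$word_order_dist[spec$grammatical_orders]
  if (!length(dist)) stop("no grammatical orders to sample from", call. = FALSE)
  dist <- dist / sum(dist)
  lex <- lexicon_forms(spec)
  with_seed(seed, {
    templates <- sample(names(dist), n_sentences, replace = TRUE, prob = dist)
    lapply(seq_len(n_sentences), function(i) {
      realize_sentence(spec, lex, templates[i])
    })
  })
}

# internal: realize one grammatical sentence from a template
realize_sentence <- function(spec, lex, template) {
  parts <- strsplit(template, "-", fixed = TRUE)[[1]]
  transitive <- all(c("A", "P") %in% parts)
  # optional agent drop, only when the reduced template is still grammatical
  if (transitive && spec$p_agent_drop > 0 &&
      stats::runif(1) < spec$p_agent_drop) {
    reduced <- paste(parts[parts != "A"], collapse = "-")
    if (reduced %in% spec$grammatical_orders) {
      parts <- parts[parts != "A"]
      template <- reduced
      transitive <- FALSE
    }
  }
  # split alignment: aspect-conditioned agent marking, aspect on the verb
  aspect <- NULL
  p_agent <- spec$p_mark_agent
  if (spec$alignment == "split") {
    aspect <- sample(c("ipfv", "pfv"), 1L)
    p_agent <- if (aspect == "pfv") 1 else 0
  }
  # accusative alignment: each transitive clause has a verb case class
  # ("acc"/"dat") marked on the verb and on overtly marked patients
  vclass <- if (spec$alignment == "accusative" && transitive) {
    sample(c("acc", "dat"), 1L)
  } else "acc"
  tokens <- character(0)
  tags <- character(0)
  for (p in parts) {
    if (p == "A" || p == "P") {
      role <- if (p == "A") "agent" else "patient"
      p_mark <- if (p == "A") p_agent else spec$p_mark_patient
      marked <- stats::runif(1) < p_mark
      sync <- marked && stats::runif(1) < spec$p_syncretic
      tokens <- c(tokens, realize_np(sample(lex$nouns, 1L), role, marked,
                                     sync, spec$alignment, vclass))
      tags <- c(tags, role)
    } else if (p == "V") {
      verb <- if (transitive) {
        v <- sample(lex$tverbs, 1L)
        if (spec$alignment == "accusative") paste0(v, ".", vclass) else v
      } else if ("A" %in% parts) {
        sample(lex$iverbs_agent, 1L)
      } else {
        sample(lex$iverbs_patient, 1L)
      }
      if (!is.null(aspect)) verb <- paste0(verb, ".", aspect)
      tokens <- c(tokens, verb)
      tags <- c(tags, "verb")
    } else if (p == "Aux") {
      # auxiliary agreement signals the role of the clause-initial NP
      initial_agent <- parts[1] == "A"
      tokens <- c(tokens, paste0(sample(lex$auxiliaries, 1L), ".",
                                 if (initial_agent) "ag" else "pt"))
      tags <- c(tags, "aux")
    }
  }
  crit <- if ("aux" %in% tags) max(which(tags == "aux")) else
    max(which(tags == "verb"))
  new_sentence(tokens, tags, crit - 1L, grammatical = TRUE)
}

#' Code the Agent Preference (reanalysis) predictor
#'
#' Classifies a condition pair of one of the three factorial designs as
#' `reanalysis` or `no_reanalysis`. Reanalysis is predicted exactly when
#' the sentence-initial noun phrase is role-ambiguous and the critical
#' word disambiguates it towards a patient: in the German-like design
#' the initial NP is always ambiguous, so the patient-initial cells are
#' reanalysis cells regardless of verb type; in the Hindi-like design
#' all items are patient-disambiguating, so the ambiguous cells are
#' reanalysis cells regardless of aspect; in the Basque-like design only
#' the ambiguous patient cell predicts reanalysis.
#'
#' @param design_name `"german_like"`, `"hindi_like"` or `"basque_like"`.
#' @param cond1,cond2 condition labels (vectorized, recycled).
#' @return character vector in `{"reanalysis", "no_reanalysis"}`.
#' @export
code_agent_preference <- function(design_name, cond1, cond2) {
  design_name <- match.arg(design_name,
                           c("german_like", "hindi_like", "basque_like"))
  lv <- design_levels(design_name)
  n <- max(length(cond1), length(cond2))
  cond1 <- rep_len(as.character(cond1), n)
  cond2 <- rep_len(as.character(cond2), n)
  if (!all(cond1 %in% lv$cond1) || !all(cond2 %in% lv$cond2)) {
    stop(sprintf(
      "unknown label combination for %s; cond1 in {%s}, cond2 in {%s}",
      design_name, paste(lv$cond1, collapse = ", "),
      paste(lv$cond2, collapse = ", ")), call. = FALSE)
  }
  ambiguous <- switch(design_name,
    german_like = rep(TRUE, n),
    hindi_like = cond1 == "ambiguous",
    basque_like = cond2 == "ambiguous")
  to_patient <- switch(design_name,
    german_like = cond1 == "patient-initial",
    hindi_like = rep(TRUE, n),
    basque_like = cond1 == "patient")
  ifelse(ambiguous & to_patient, "reanalysis", "no_reanalysis")
}

# internal: condition labels of each factorial design
design_levels <- function(design_name) {
  switch(design_name,
    german_like = list(cond1 = c("agent-initial", "patient-initial"),
                       cond2 = c("accusative", "dative")),
    hindi_like = list(cond1 = c("ambiguous", "unambiguous"),
                      cond2 = c("imperfective", "perfective")),
    basque_like = list(cond1 = c("agent", "patient"),
                       cond2 = c("ambiguous", "unambiguous")),
    stop("unsupported design: ", design_name, call. = FALSE))
}

#' Generate a 2x2 factorial stimulus set
#'
#' Builds `n_items` experimental items, each realized in all four cells
#' of the design's 2x2 condition cross, with lemmas shared across cells
#' of an item so that only the condition manipulation changes surface
#' forms. Every item carries the binary Agent Preference (reanalysis)
#' coding of its cell.
#'
#' Designs: `german_like` crosses initial NP role (agent-/patient-initial)
#' with verb type (accusative/dative); sentences are NP NP V Aux with a
#' role-ambiguous initial NP disambiguated at the final auxiliary.
#' `hindi_like` crosses ambiguity with aspect; all items are
#' patient-initial (NP V NP, afterthought agent) and the critical main
#' verb disambiguates the initial NP to patient. `basque_like` crosses
#' subject role (agent/patient, assigned by intransitive verb class)
#' with ambiguity; sentences are NP V and ambiguous-cell NPs carry a
#' surface-syncretic case form identical across roles.
#'
#' @param spec a [language_spec()]; supplies the lexicon and syncretism
#'   convention.
#' @param design_name `"german_like"`, `"hindi_like"` or `"basque_like"`.
#' @param n_items number of items (default 40).
#' @param seed integer seed.
#' @return an object of class `stimulus_set`: a list with `design_name`
#'   and `items`, a data.frame with columns `item_id`, `cond1`, `cond2`,
#'   `reanalysis` and a list-column `sentence`.
#' @export
generate_stimuli <- function(spec, design_name, n_items = 40L, seed = 1L) {
  stopifnot(inherits(spec, "language_spec"), n_items >= 1)
  design_name <- match.arg(design_name,
                           c("german_like", "hindi_like", "basque_like"))
  lv <- design_levels(design_name)
  lex <- lexicon_forms(spec)
  rows <- with_seed(seed, {
    out <- list()
    for (i in seq_len(n_items)) {
      item_id <- sprintf("%s_item%03d", sub("_like$", "", design_name), i)
      lemmas <- list(
        noun1 = sample(lex$nouns, 1L),
        noun2 = sample(lex$nouns, 1L),
        tverb = sample(lex$tverbs, 1L),
        iverb_a = sample(lex$iverbs_agent, 1L),
        iverb_p = sample(lex$iverbs_patient, 1L),
        aux = sample(lex$auxiliaries, 1L))
      while (lemmas$noun2 == lemmas$noun1) lemmas$noun2 <- sample(lex$nouns, 1L)
      for (c1 in lv$cond1) {
        for (c2 in lv$cond2) {
          sen <- realize_stimulus(design_name, lemmas, c1, c2)
          sen$item_id <- item_id
          out[[length(out) + 1L]] <- list(item_id = item_id, cond1 = c1,
                                          cond2 = c2, sentence = sen)
        }
      }
    }
    out
  })
  items <- data.frame(
    item_id = vapply(rows, `[[`, "", "item_id"),
    cond1 = vapply(rows, `[[`, "", "cond1"),
    cond2 = vapply(rows, `[[`, "", "cond2"),
    stringsAsFactors = FALSE)
  items$reanalysis <- as.integer(
    code_agent_preference(design_name, items$cond1, items$cond2) ==
      "reanalysis")
  items$sentence <- lapply(rows, `[[`, "sentence")
  structure(list(design_name = design_name, items = items),
            class = "stimulus_set")
}

# internal: realize one stimulus sentence for one design cell
realize_stimulus <- function(design_name, lemmas, cond1, cond2) {
  switch(design_name,
    german_like = {
      # NP1 NP2 V Aux; NP1 role-ambiguous (bare), NP2 case-marked for its
      # role; verb type varies with cond2; aux agreement disambiguates NP1
      roles <- if (cond1 == "agent-initial") c("agent", "patient") else
        c("patient", "agent")
      np1 <- lemmas$noun1  # bare = role-ambiguous
      np2 <- if (roles[2] == "agent") lemmas$noun2 else  # agents unmarked
        paste0(lemmas$noun2, "-", substr(cond2, 1, 3))
      verb <- paste0(lemmas$tverb, ".", substr(cond2, 1, 3))
      aux <- paste0(lemmas$aux, ".", if (cond1 == "agent-initial") "ag" else
        "pt")
      new_sentence(c(np1, np2, verb, aux), c(roles, "verb", "aux"), 3L, TRUE)
    },
    hindi_like = {
      # P V A (afterthought agent); critical verb at position 1
      np1 <- if (cond1 == "ambiguous") lemmas$noun1 else
        paste0(lemmas$noun1, "-ko")
      asp <- if (cond2 == "perfective") "pfv" else "ipfv"
      verb <- paste0(lemmas$tverb, ".", asp)
      np2 <- if (asp == "pfv") paste0(lemmas$noun2, "-erg") else lemmas$noun2
      new_sentence(c(np1, verb, np2), c("patient", "verb", "agent"), 1L, TRUE)
    },
    basque_like = {
      # NP V; verb class assigns the subject role
      role <- cond1
      np <- if (cond2 == "ambiguous") paste0(lemmas$noun1, "-x") else
        if (role == "agent") paste0(lemmas$noun1, "-erg") else lemmas$noun1
      verb <- if (role == "agent") lemmas$iverb_a else lemmas$iverb_p
      new_sentence(c(np, verb), c(role, "verb"), 1L, TRUE)
    })
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set %s: %d items x 4 cells = %d sentences>\n",
              x$design_name, length(unique(x$items$item_id)),
              nrow(x$items)))
  invisible(x)
}

#' Ungrammatical constituent-order permutations of a sentence
#'
#' Enumerates reorderings of the sentence's constituents, discards any
#' whose template is among the spec's grammatical orders (or identical
#' to the original token sequence), and returns `k` of them, sampled
#' reproducibly under the seed. The critical index is re-annotated to
#' the critical word's new position. If fewer than `k` ungrammatical
#' orders exist, all existing ones are returned with a warning.
#'
#' @param sentence a grammatical `n400_sentence`.
#' @param spec the [language_spec()] defining grammatical orders.
#' @param k number of variants requested, between 2 and 4.
#' @param seed integer seed.
#' @return list of ungrammatical `n400_sentence` objects (possibly
#'   shorter than `k`, possibly empty).
#' @export
permute_ungrammatical <- function(sentence, spec, k = 2L, seed = 1L) {
  stopifnot(inherits(sentence, "n400_sentence"), k >= 2, k <= 4)
  if (!sentence$grammatical) {
    stop("`sentence` must be grammatical", call. = FALSE)
  }
  n <- length(sentence$tokens)
  perms <- permutations_of(n)
  crit1 <- sentence$critical_index + 1L
  orig <- paste(sentence$tokens, collapse = " ")
  seen <- character(0)
  candidates <- list()
  for (r in seq_len(nrow(perms))) {
    idx <- perms[r, ]
    toks <- sentence$tokens[idx]
    key <- paste(toks, collapse = " ")
    if (key == orig || key %in% seen) next
    tags <- sentence$role_tags[idx]
    if (template_of(tags) %in% spec$grammatical_orders) next
    seen <- c(seen, key)
    v <- new_sentence(toks, tags, which(idx == crit1) - 1L,
                      grammatical = FALSE, item_id = sentence$item_id)
    candidates[[length(candidates) + 1L]] <- v
  }
  if (length(candidates) < k) {
    warning(sprintf("only %d ungrammatical order(s) exist (requested %d)",
                    length(candidates), k), call. = FALSE)
    return(candidates)
  }
  with_seed(seed, candidates[sort(sample.int(length(candidates), k))])
}

# internal: all permutations of 1..n as a matrix (n <= 7)
permutations_of <- function(n) {
  stopifnot(n >= 1, n <= 7)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (i in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[r, ] <- c(i, rest[sub[s, ]])
      r <- r + 1L
    }
  }
  out
}

#' Read and write corpora and stimulus tables
#'
#' Corpora are stored as plain text, one sentence per line with
#' space-separated tokens. Stimulus sets are stored as TSV with columns
#' `item_id`, `cond1`, `cond2`, `reanalysis`, `critical_index` (0-based),
#' `tokens` (space-joined) and `role_tags` (comma-joined).
#'
#' @param corpus list of `n400_sentence` objects.
#' @param path file path.
#' @return `write_*` return the path invisibly; `read_corpus` returns a
#'   character vector of token strings, `read_stimuli` a data.frame.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, function(s) paste(s$tokens, collapse = " "), ""),
             con = path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) readLines(path, encoding = "UTF-8")

#' @rdname write_corpus
#' @param stimuli a `stimulus_set`.
#' @export
write_stimuli <- function(stimuli, path) {
  df <- stimuli_table(stimuli)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_stimuli <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Flatten a stimulus set to a plain data.frame
#'
#' @param stimuli a `stimulus_set`.
#' @return data.frame with one row per item x cell and the columns of
#'   the TSV interchange format.
#' @export
stimuli_table <- function(stimuli) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  it <- stimuli$items
  data.frame(
    item_id = it$item_id, cond1 = it$cond1, cond2 = it$cond2,
    reanalysis = it$reanalysis,
    critical_index = vapply(it$sentence, function(s) s$critical_index, 0L),
    tokens = vapply(it$sentence,
                    function(s) paste(s$tokens, collapse = " "), ""),
    role_tags = vapply(it$sentence,
                       function(s) paste(s$role_tags, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Read and write language specifications as YAML or JSON
#'
#' The format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`).
#'
#' @param spec a [language_spec()].
#' @param path file path.
#' @return `write_language_spec` returns the path invisibly;
#'   `read_language_spec` returns a `language_spec`.
#' @export
write_language_spec <- function(spec, path) {
  stopifnot(inherits(spec, "language_spec"))
  x <- unclass(spec)
  x$word_order_dist <- as.list(x$word_order_dist)
  x$lexicon_sizes <- as.list(stats::setNames(spec$lexicon_sizes,
                                             attr(spec, "names_lexicon")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_language_spec
#' @export
read_language_spec <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  language_spec(alignment = x$alignment,
                p_mark_agent = x$p_mark_agent,
                p_mark_patient = x$p_mark_patient,
                p_syncretic = x$p_syncretic,
                word_order_dist = unlist(x$word_order_dist),
                p_agent_drop = x$p_agent_drop,
                lexicon_sizes = unlist(x$lexicon_sizes),
                grammatical_orders = unlist(x$grammatical_orders))
}
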