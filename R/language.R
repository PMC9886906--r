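#' Specify an artificial language
#'
#' A language specification fixes everything [build_language()] needs to
#' generate a monosyllabic artificial lexicon: the alphabet (with a designated
#' vowel class), the onset and rime inventories, the fraction of words whose
#' rime pronunciation deviates from its family majority, the Zipf exponent of
#' the word-frequency distribution, the sparse binary semantic space, and the
#' number of homophone pairs (distinct meanings sharing one spoken form,
#' disambiguated by context units).
#'
#' @param n_words number of lexical items (meanings), including homophone twins.
#' @param alphabet_size number of letters (at most 26).
#' @param n_vowel_letters how many letters form the vowel class; the remainder
#'   are consonants. Each letter maps to one phoneme.
#' @param n_onsets,n_rimes sizes of the onset (1-3 consonants) and rime
#'   (vowel + 0-2 coda consonants) spelling inventories.
#' @param exception_fraction proportion of words whose rime is pronounced
#'   irregularly (a minority pronunciation within its rime-spelling family).
#' @param zipf_exponent exponent of the rank-frequency power law.
#' @param n_sem_features size of the binary semantic feature space.
#' @param sem_features_per_word integer range; the per-word number of active
#'   features is drawn uniformly from it and doubles as the imageability proxy.
#' @param n_homophone_pairs number of homophone pairs.
#' @param seed integer seed controlling generation.
#' @return An object of class `language_spec`.
#' @export
language_spec <- function(n_words = 300, alphabet_size = 10, n_vowel_letters = 3,
                          n_onsets = 25, n_rimes = 30,
                          exception_fraction = 0.2, zipf_exponent = 1,
                          n_sem_features = 50, sem_features_per_word = c(2, 8),
                          n_homophone_pairs = 2, seed = 1) {
  stopifnot(length(sem_features_per_word) == 2)
  spec <- list(n_words = as.integer(n_words),
               alphabet_size = as.integer(alphabet_size),
               n_vowel_letters = as.integer(n_vowel_letters),
               n_onsets = as.integer(n_onsets), n_rimes = as.integer(n_rimes),
               exception_fraction = exception_fraction,
               zipf_exponent = zipf_exponent,
               n_sem_features = as.integer(n_sem_features),
               sem_features_per_word = as.integer(sem_features_per_word),
               n_homophone_pairs = as.integer(n_homophone_pairs),
               seed = as.integer(seed))
  class(spec) <- "language_spec"
  validate_language_spec(spec)
  spec
}

validate_language_spec <- function(spec) {
  with(spec, {
    if (exception_fraction < 0 || exception_fraction >= 1)
      stop("exception_fraction must lie in [0, 1)")
    if (alphabet_size > 26 || alphabet_size < 3)
      stop("alphabet_size must lie in [3, 26]")
    if (n_vowel_letters < 1 || n_vowel_letters >= alphabet_size)
      stop("n_vowel_letters must leave at least one consonant")
    counts <- c(n_words, n_onsets, n_rimes, n_sem_features, zipf_exponent)
    if (any(counts <= 0)) stop("all counts must be positive")
    if (any(sem_features_per_word < 1) ||
        sem_features_per_word[1] > sem_features_per_word[2])
      stop("sem_features_per_word must be an increasing positive range")
    if (n_sem_features < sem_features_per_word[2])
      stop("n_sem_features must be at least the maximum features per word")
    if (n_homophone_pairs < 0 || 2 * n_homophone_pairs > n_words)
      stop("too many homophone pairs for n_words")
    if (n_words - n_homophone_pairs > n_onsets * n_rimes)
      stop("infeasible spec: more words than onset x rime combinations")
  })
  invisible(spec)
}

#' @export
print.language_spec <- function(x, ...) {
  cat("<language_spec>", x$n_words, "words,", x$n_onsets, "onsets x",
      x$n_rimes, "rimes, exception fraction", x$exception_fraction,
      ", seed", x$seed, "\n")
  invisible(x)
}

# distinct random phoneme feature vectors (25 binary features, k active)
make_inventory <- function(labels, n_features = 25, k_active = 8) {
  inv <- matrix(0, n_features, length(labels) + 1,
                dimnames = list(NULL, c("<null>", labels)))
  seen <- character(0)
  for (j in seq_along(labels)) {
    repeat {
      v <- sort(sample.int(n_features, k_active))
      key <- paste(v, collapse = ",")
      if (!key %in% seen) { seen <- c(seen, key); break }
    }
    inv[v, j + 1] <- 1
  }
  inv
}

sample_strings <- function(n, chars, len_probs, max_tries = 20000) {
  out <- character(0)
  tries <- 0
  while (length(out) < n) {
    len <- sample.int(length(len_probs), 1, prob = len_probs)
    s <- paste(sample(chars, len, replace = TRUE), collapse = "")
    if (!s %in% out) out <- c(out, s)
    tries <- tries + 1
    if (tries > max_tries) stop("could not generate enough distinct strings")
  }
  out
}

#' Generate an artificial lexicon
#'
#' Builds a lexicon of monosyllabic words (onset + rime) with slot-compatible
#' orthography and phonology, Zipfian word frequencies, a controlled fraction
#' of rime-exception words, sparse binary semantics whose per-word feature
#' count serves as an imageability proxy, and homophone pairs tagged with
#' distinct context indices. Letters map one-to-one to phonemes; exception
#' words replace their rime vowel phoneme with an alternative vowel, so their
#' rime pronunciation is a minority within the rime-spelling family.
#'
#' @param spec a [language_spec()].
#' @return An object of class `lexicon`: a list with `items` (one row per
#'   lexical item with covariates `wf`, `log_wf`, `ons`, `rc`, `img`,
#'   `context_index`), the phoneme `inventory` (25 binary features per phoneme,
#'   first column the all-zero null phoneme), and the generating structures.
#' @export
build_language <- function(spec) {
  validate_language_spec(spec)
  set.seed(spec$seed)
  ab <- letters[seq_len(spec$alphabet_size)]
  vowels <- ab[seq_len(spec$n_vowel_letters)]
  consonants <- setdiff(ab, vowels)
  inventory <- make_inventory(ab)

  onsets <- sample_strings(spec$n_onsets, consonants, c(0.6, 0.3, 0.1))
  # rime = vowel + coda (coda may be empty)
  rimes <- character(0)
  tries <- 0
  while (length(rimes) < spec$n_rimes) {
    v <- sample(vowels, 1)
    clen <- sample.int(3, 1, prob = c(0.3, 0.5, 0.2)) - 1L
    r <- paste0(v, paste(sample(consonants, clen, replace = TRUE), collapse = ""))
    if (!r %in% rimes) rimes <- c(rimes, r)
    tries <- tries + 1
    if (tries > 20000) stop("could not generate enough distinct rimes")
  }

  # regular pronunciation: identity letter-to-phoneme; irregular: swap vowel
  irregular_vowel <- vapply(rimes, function(r) {
    v <- substr(r, 1, 1)
    sample(setdiff(vowels, v), 1)
  }, character(1))

  n_base <- spec$n_words - spec$n_homophone_pairs
  combos <- expand.grid(onset = onsets, rime = rimes, stringsAsFactors = FALSE)
  pick <- sample.int(nrow(combos), n_base)
  words <- combos[pick, , drop = FALSE]
  rownames(words) <- NULL

  # assign exceptions family by family (random order), keeping a strict
  # minority within each inconsistent family; families visited late stay fully
  # consistent, giving the bimodal consistency structure natural languages show
  n_exc <- round(spec$exception_fraction * n_base)
  fam_size <- table(words$rime)
  is_exc <- rep(FALSE, n_base)
  if (n_exc > 0) {
    cap <- pmax(ceiling(fam_size / 2) - 1L, 0L)
    if (sum(cap) < n_exc)
      stop("cannot realise exception_fraction: rime families too small")
    remaining <- n_exc
    for (fam in sample(names(fam_size))) {
      if (remaining == 0) break
      take <- min(cap[[fam]], remaining)
      if (take == 0) next
      members <- which(words$rime == fam)
      is_exc[sample(members, take)] <- TRUE
      remaining <- remaining - take
    }
  }

  split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
  pron_of <- function(onset, rime, irregular) {
    ph <- c(split_chars(onset), split_chars(rime))
    if (irregular) ph[nchar(onset) + 1L] <- irregular_vowel[[rime]]
    ph
  }
  phonemes <- mapply(function(o, r, e) paste(pron_of(o, r, e), collapse = " "),
                     words$onset, words$rime, is_exc, USE.NAMES = FALSE)
  rime_phon <- mapply(function(o, r, e) {
    ph <- pron_of(o, r, e)
    paste(ph[(nchar(o) + 1L):length(ph)], collapse = " ")
  }, words$onset, words$rime, is_exc, USE.NAMES = FALSE)

  items <- data.frame(id = seq_len(n_base),
                      letters = paste0(words$onset, words$rime),
                      onset = words$onset, rime = words$rime,
                      phonemes = phonemes, rime_phon = rime_phon,
                      is_exception = is_exc,
                      context_index = 0L,
                      stringsAsFactors = FALSE)

  # homophone twins: same spelling and pronunciation, different meaning,
  # distinguished by context units
  if (spec$n_homophone_pairs > 0) {
    base_idx <- sample.int(n_base, spec$n_homophone_pairs)
    twins <- items[base_idx, , drop = FALSE]
    for (k in seq_len(spec$n_homophone_pairs)) {
      ctx <- sample.int(4, 2)
      items$context_index[base_idx[k]] <- ctx[1]
      twins$context_index[k] <- ctx[2]
    }
    twins$id <- n_base + seq_len(spec$n_homophone_pairs)
    items <- rbind(items, twins)
    rownames(items) <- NULL
  }
  n_items <- nrow(items)

  # semantics: unique feature sets; homophone twins disjoint from partners
  rng <- spec$sem_features_per_word
  sem_sets <- vector("list", n_items)
  seen <- character(0)
  partner <- rep(NA_integer_, n_items)
  if (spec$n_homophone_pairs > 0) {
    twin_rows <- (n_base + 1):n_items
    base_rows <- match(items$letters[twin_rows], items$letters[seq_len(n_base)])
    partner[twin_rows] <- base_rows
  }
  for (i in seq_len(n_items)) {
    repeat {
      k <- sample(rng[1]:rng[2], 1)
      v <- sort(sample.int(spec$n_sem_features, k))
      key <- paste(v, collapse = ",")
      ok <- !key %in% seen
      if (ok && !is.na(partner[i]))
        ok <- length(intersect(v, sem_sets[[partner[i]]])) == 0
      if (ok) { seen <- c(seen, key); sem_sets[[i]] <- v; break }
    }
  }
  items$sem <- vapply(sem_sets, paste, character(1), collapse = ",")
  items$img <- lengths(sem_sets)

  # Zipfian frequencies over items
  rank <- sample.int(n_items)
  wf <- rank^(-spec$zipf_exponent)
  items$wf <- wf / sum(wf)
  items$log_wf <- log(items$wf * 1e6 + 1)

  lex <- structure(list(items = items, inventory = inventory,
                        vowel_letters = vowels, consonant_letters = consonants,
                        onsets = onsets, rimes = rimes,
                        irregular_vowel = irregular_vowel, spec = spec),
                   class = "lexicon")
  lex$items$rc <- vapply(seq_len(n_items), function(i) rime_consistency(lex, i),
                         numeric(1))
  lex$items$ons <- vapply(seq_len(n_items), function(i) orth_neighbourhood(lex, i),
                          numeric(1))
  lex
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon>", nrow(x$items), "items;",
      sum(x$items$is_exception), "exception words;",
      sum(x$items$context_index > 0) / 2, "homophone pairs\n")
  invisible(x)
}

#' Rime consistency of a lexical item
#'
#' Type-based consistency including the word itself: the number of words that
#' share the item's rime spelling and its rime pronunciation, divided by the
#' number of words sharing the rime spelling (friends / (friends + enemies)).
#' Homophone twins count once per lexical item.
#'
#' @param lexicon a `lexicon`.
#' @param item row index of the item.
#' @return A proportion in (0, 1].
#' @export
rime_consistency <- function(lexicon, item) {
  it <- lexicon$items[item, ]
  fam <- lexicon$items$rime == it$rime
  sum(fam & lexicon$items$rime_phon == it$rime_phon) / sum(fam)
}

#' Orthographic neighbourhood size (Coltheart's N)
#'
#' Number of other words of the same length differing in exactly one letter.
#' Items sharing an identical spelling (homophone twins) are not neighbours.
#'
#' @inheritParams rime_consistency
#' @return A count.
#' @export
orth_neighbourhood <- function(lexicon, item) {
  w <- lexicon$items$letters[item]
  others <- unique(lexicon$items$letters)
  others <- others[others != w & nchar(others) == nchar(w)]
  if (length(others) == 0) return(0L)
  a <- strsplit(w, "")[[1]]
  sum(vapply(strsplit(others, ""), function(b) sum(a != b) == 1L, logical(1)))
}

#' Frequency-weighted word sampling
#'
#' Draws item indices with replacement with probability equal to normalized
#' word frequency, optionally restricted to the `vocab_size` most frequent
#' words (the construction used for oral vocabulary conditions).
#'
#' @param lexicon a `lexicon`.
#' @param n number of draws.
#' @param vocab_size optional; restrict to the top-`vocab_size` words by
#'   frequency.
#' @return Integer item indices.
#' @export
sample_word <- function(lexicon, n = 1, vocab_size = NULL) {
  idx <- top_vocabulary(lexicon, vocab_size)
  idx[sample.int(length(idx), n, replace = TRUE,
                 prob = lexicon$items$wf[idx])]
}

#' Indices of the most frequent words
#'
#' @param lexicon a `lexicon`.
#' @param k vocabulary size; `NULL` means the whole lexicon.
#' @return Integer item indices, in decreasing frequency order.
#' @export
top_vocabulary <- function(lexicon, k = NULL) {
  ord <- order(-lexicon$items$wf, lexicon$items$id)
  if (is.null(k)) return(ord)
  if (k > nrow(lexicon$items)) stop("vocabulary size exceeds lexicon size")
  ord[seq_len(k)]
}

item_phonemes <- function(lexicon, item) {
  strsplit(lexicon$items$phonemes[item], " ", fixed = TRUE)[[1]]
}

item_sem_features <- function(lexicon, item) {
  as.integer(strsplit(lexicon$items$sem[item], ",", fixed = TRUE)[[1]])
}

#' Generate nonwords from unused onset-rime combinations
#'
#' Consistent nonwords use rimes from fully consistent families; their single
#' acceptable pronunciation is the family pronunciation. Inconsistent nonwords
#' use rimes whose families contain exception words; every attested family
#' pronunciation of the rime is acceptable.
#'
#' @param lexicon a `lexicon`.
#' @param n number of nonwords.
#' @param condition `"consistent"` or `"inconsistent"`.
#' @param seed integer seed.
#' @return A data frame with `letters`, `condition` and a list column
#'   `acceptable` of phoneme-label vectors.
#' @export
generate_nonwords <- function(lexicon, n, condition = c("consistent", "inconsistent"),
                              seed = 1) {
  condition <- match.arg(condition)
  set.seed(seed)
  items <- lexicon$items
  fam_pron <- split(items$rime_phon, items$rime)
  n_pron <- vapply(fam_pron, function(p) length(unique(p)), integer(1))
  eligible <- if (condition == "consistent") names(n_pron)[n_pron == 1]
              else names(n_pron)[n_pron >= 2]
  combos <- expand.grid(onset = lexicon$onsets, rime = eligible,
                        stringsAsFactors = FALSE)
  combos$letters <- paste0(combos$onset, combos$rime)
  combos <- combos[!combos$letters %in% items$letters, , drop = FALSE]
  if (nrow(combos) < n)
    stop("insufficient unused onset x rime combinations for ", condition,
         " nonwords")
  pick <- combos[sample.int(nrow(combos), n), , drop = FALSE]
  acceptable <- lapply(seq_len(n), function(i) {
    on_ph <- strsplit(pick$onset[i], "")[[1]]
    prons <- unique(fam_pron[[pick$rime[i]]])
    lapply(prons, function(rp) c(on_ph, strsplit(rp, " ", fixed = TRUE)[[1]]))
  })
  out <- data.frame(letters = pick$letters, condition = condition,
                    stringsAsFactors = FALSE)
  out$acceptable <- acceptable
  rownames(out) <- NULL
  out
}
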