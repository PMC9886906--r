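#' Slot-based orthographic encoding
#'
#' Encodes a letter string into 14 letter slots of `alphabet_size` units each.
#' The first vowel occupies slot 5 and a second vowel slot 6; consonants
#' preceding the first vowel fill the slots adjacent to it (right-aligned into
#' slots 1-4) and consonants following the vowel(s) fill the slots immediately
#' after, left-aligned. Exactly one unit is active per occupied slot.
#'
#' @param lexicon a `lexicon` (defines the alphabet and vowel class).
#' @param letters a single word string.
#' @param n_slots number of letter slots.
#' @return A binary vector of length `n_slots * alphabet_size`.
#' @export
encode_orthography <- function(lexicon, letters, n_slots = 14) {
  ab_size <- lexicon$spec$alphabet_size
  ab <- base::letters[seq_len(ab_size)]
  ch <- strsplit(letters, "", fixed = TRUE)[[1]]
  li <- match(ch, ab)
  if (anyNA(li)) stop("word '", letters, "' uses letters outside the alphabet")
  is_v <- ch %in% lexicon$vowel_letters
  vpos <- which(is_v)
  if (length(vpos) == 0) stop("word '", letters, "' has no vowel")
  if (length(vpos) > 2) stop("word '", letters, "' has more than two vowels")
  if (length(vpos) == 2 && vpos[2] != vpos[1] + 1)
    stop("word '", letters, "' has non-adjacent vowels")
  pre <- seq_len(vpos[1] - 1)
  post <- if (max(vpos) < length(ch)) (max(vpos) + 1):length(ch) else integer(0)
  if (length(pre) > 4)
    stop("word '", letters, "' overflows the pre-vowel slots (max 4 consonants)")
  slots <- integer(length(ch))
  slots[vpos[1]] <- 5L
  if (length(vpos) == 2) slots[vpos[2]] <- 6L
  if (length(pre) > 0) slots[pre] <- 4L - rev(seq_along(pre)) + 1L
  post_start <- if (length(vpos) == 2) 7L else 6L
  if (length(post) > 0) {
    slots[post] <- post_start + seq_along(post) - 1L
    if (max(slots) > n_slots)
      stop("word '", letters, "' overflows the post-vowel slots")
  }
  out <- numeric(n_slots * ab_size)
  out[(slots - 1L) * ab_size + li] <- 1
  out
}

#' Slot-based phonological encoding
#'
#' Encodes a phoneme sequence into 8 slots of 25 phonological-feature units.
#' Slots 1-3 hold onset consonants right-aligned against the vowel, slot 4 the
#' single vowel, and slots 5-8 coda consonants left-aligned. Empty slots are
#' all-zero (the null phoneme).
#'
#' @param lexicon a `lexicon` (defines the phoneme inventory and vowel class).
#' @param phonemes character vector of phoneme labels.
#' @return A binary vector of length `8 * 25`.
#' @export
encode_phonology <- function(lexicon, phonemes) {
  inv <- lexicon$inventory
  if (!all(phonemes %in% colnames(inv)))
    stop("phoneme(s) not in inventory: ",
         paste(setdiff(phonemes, colnames(inv)), collapse = ", "))
  is_v <- phonemes %in% lexicon$vowel_letters
  vpos <- which(is_v)
  if (length(vpos) != 1) stop("syllable must contain exactly one vowel phoneme")
  onset <- phonemes[seq_len(vpos - 1)]
  coda <- if (vpos < length(phonemes)) phonemes[(vpos + 1):length(phonemes)]
          else character(0)
  if (length(onset) > 3) stop("more than three onset consonants")
  if (length(coda) > 4) stop("more than four coda consonants")
  slots <- rep("<null>", 8)
  if (length(onset) > 0) slots[(3 - length(onset) + 1):3] <- onset
  slots[4] <- phonemes[vpos]
  if (length(coda) > 0) slots[4 + seq_along(coda)] <- coda
  as.numeric(inv[, slots])
}

#' Binary semantic encoding
#'
#' @param features integer indices (1-based) of active semantic features.
#' @param n_sem_features size of the semantic feature space.
#' @return A binary vector whose sum equals the imageability proxy.
#' @export
encode_semantics <- function(features, n_sem_features) {
  if (length(features) == 0) stop("a word must have at least one semantic feature")
  if (any(features < 1 | features > n_sem_features))
    stop("semantic feature index out of range")
  out <- numeric(n_sem_features)
  out[features] <- 1
  out
}

#' Context-unit encoding
#'
#' @param context_index 0 for non-homophones (no context unit active) or 1-4.
#' @return A binary vector of length 4.
#' @export
encode_context <- function(context_index) {
  out <- numeric(4)
  if (context_index > 0) out[context_index] <- 1
  out
}

#' Encode every lexical item
#'
#' @param lexicon a `lexicon`.
#' @return A list of matrices `O`, `P`, `S`, `C` with one column per item.
#' @export
lexicon_encodings <- function(lexicon) {
  n <- nrow(lexicon$items)
  O <- vapply(seq_len(n),
              function(i) encode_orthography(lexicon, lexicon$items$letters[i]),
              numeric(14 * lexicon$spec$alphabet_size))
  P <- vapply(seq_len(n),
              function(i) encode_phonology(lexicon, item_phonemes(lexicon, i)),
              numeric(8 * 25))
  S <- vapply(seq_len(n),
              function(i) encode_semantics(item_sem_features(lexicon, i),
                                           lexicon$spec$n_sem_features),
              numeric(lexicon$spec$n_sem_features))
  C <- vapply(lexicon$items$context_index, encode_context, numeric(4))
  list(O = O, P = P, S = S, C = C)
}

#' Target phoneme slot labels for a phoneme sequence
#'
#' @param lexicon a `lexicon`.
#' @param phonemes character vector of phoneme labels.
#' @return Character vector of 8 slot labels (with `"<null>"` for empty slots).
#' @export
phoneme_slots <- function(lexicon, phonemes) {
  is_v <- phonemes %in% lexicon$vowel_letters
  vpos <- which(is_v)
  onset <- phonemes[seq_len(vpos - 1)]
  coda <- if (vpos < length(phonemes)) phonemes[(vpos + 1):length(phonemes)]
          else character(0)
  slots <- rep("<null>", 8)
  if (length(onset) > 0) slots[(3 - length(onset) + 1):3] <- onset
  slots[4] <- phonemes[vpos]
  if (length(coda) > 0) slots[4 + seq_along(coda)] <- coda
  slots
}

#' Serialize a lexicon to plain-text TSV files
#'
#' Writes `<stem>_items.tsv` (one row per item: letters, phonemes, semantic
#' feature indices, covariates, context index) and `<stem>_inventory.tsv`
#' (one row per phoneme: label, class, 25 binary features).
#'
#' @param lexicon a `lexicon`.
#' @param stem file path stem.
#' @return The stem, invisibly.
#' @export
write_lexicon <- function(lexicon, stem) {
  write.table(lexicon$items, paste0(stem, "_items.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  inv <- lexicon$inventory
  cls <- ifelse(colnames(inv) == "<null>", "null",
                ifelse(colnames(inv) %in% lexicon$vowel_letters, "vowel",
                       "consonant"))
  inv_df <- data.frame(label = colnames(inv), class = cls,
                       t(inv), check.names = FALSE)
  names(inv_df)[-(1:2)] <- paste0("f", 1:25)
  write.table(inv_df, paste0(stem, "_inventory.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' Load a lexicon written by [write_lexicon()]
#'
#' Rebuilds the lexicon from the two TSV files; generator-only structures
#' (onset/rime inventories) are reconstructed from the attested items.
#'
#' @param stem file path stem used when writing.
#' @param spec optionally, the original [language_spec()].
#' @return A `lexicon`.
#' @export
read_lexicon <- function(stem, spec = NULL) {
  items <- read.delim(paste0(stem, "_items.tsv"), stringsAsFactors = FALSE)
  inv_df <- read.delim(paste0(stem, "_inventory.tsv"), check.names = FALSE,
                       stringsAsFactors = FALSE)
  inv <- t(as.matrix(inv_df[, paste0("f", 1:25)]))
  colnames(inv) <- inv_df$label
  rownames(inv) <- NULL
  vowels <- inv_df$label[inv_df$class == "vowel"]
  consonants <- inv_df$label[inv_df$class == "consonant"]
  if (is.null(spec)) {
    n_sem <- max(vapply(strsplit(items$sem, ","), function(x) max(as.integer(x)),
                        integer(1)))
    spec <- list(alphabet_size = length(vowels) + length(consonants),
                 n_sem_features = n_sem, n_words = nrow(items))
  }
  structure(list(items = items, inventory = inv, vowel_letters = vowels,
                 consonant_letters = consonants,
                 onsets = unique(items$onset), rimes = unique(items$rime),
                 irregular_vowel = NULL, spec = spec),
            class = "lexicon")
}
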