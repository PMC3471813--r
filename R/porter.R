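#' Porter suffix-stripping stemmer
#'
#' Reduces English words to stems by the original Porter (1980) algorithm:
#' five sequential rule steps driven by the consonant/vowel "measure" of the
#' stem. Used throughout the package to collapse morphological variants
#' ("transcriptional", "transcription" -> "transcript") so that term
#' frequencies aggregate over word forms rather than surface strings.
#'
#' Words of one or two letters are returned unchanged. Input is expected to
#' be lower-case alphabetic; the function does not tokenize.
#'
#' @param words character vector of lower-case words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("transcriptional", "regulation", "ponies", "agreed"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_word, character(1), USE.NAMES = FALSE)
}

# vowel classification per position: a,e,i,o,u are vowels; y is a vowel
# when preceded by a consonant (so "syzygy" scans CVCVCV)
.pt_vowel_map <- function(chars) {
  v <- logical(length(chars))
  for (i in seq_along(chars)) {
    if (chars[i] %in% c("a", "e", "i", "o", "u")) {
      v[i] <- TRUE
    } else if (chars[i] == "y" && i > 1L && !v[i - 1L]) {
      v[i] <- TRUE
    }
  }
  v
}

# the measure m of [C](VC)^m[V]: number of vowel-run -> consonant-run
# transitions
.pt_measure <- function(w) {
  if (!nzchar(w)) return(0L)
  v <- .pt_vowel_map(strsplit(w, "", fixed = TRUE)[[1L]])
  r <- rle(v)$values
  if (length(r) < 2L) return(0L)
  sum(r[-length(r)] & !r[-1L])
}

.pt_has_vowel <- function(w) {
  nzchar(w) && any(.pt_vowel_map(strsplit(w, "", fixed = TRUE)[[1L]]))
}

# *d: ends with a double consonant (e.g. -tt, -ss)
.pt_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  ch[n] == ch[n - 1L] && !.pt_vowel_map(ch)[n]
}

# *o: ends consonant-vowel-consonant where the final consonant is not w, x, y
.pt_ends_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  v <- .pt_vowel_map(ch)
  !v[n - 2L] && v[n - 1L] && !v[n] && !(ch[n] %in% c("w", "x", "y"))
}

.pt_ends <- function(w, suffix) {
  ns <- nchar(suffix)
  nchar(w) > ns && substring(w, nchar(w) - ns + 1L) == suffix
}

.pt_chop <- function(w, k) substr(w, 1L, nchar(w) - k)

# rule tables for steps 2-4; within a step the longest matching suffix wins
# and no other rule is tried (original 1980 rule set, without the later
# -logi addendum)
.pt_step2_rules <- list(
  c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"),
  c("tional", "tion"), c("biliti", "ble"),
  c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
  c("ousli", "ous"), c("entli", "ent"), c("iviti", "ive"),
  c("enci", "ence"), c("anci", "ance"), c("izer", "ize"),
  c("abli", "able"), c("alli", "al"), c("ator", "ate"),
  c("eli", "e")
)

.pt_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"),
  c("iciti", "ic"), c("ical", "ic"), c("ful", ""), c("ness", "")
)

.pt_step4_suffixes <- c(
  "ement", "ance", "ence", "able", "ible", "ment",
  "ant", "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
  "al", "er", "ic", "ou"
)

porter_stem_word <- function(w) {
  if (is.na(w) || nchar(w) <= 2L) return(w)

  # step 1a: plurals
  if (.pt_ends(w, "sses")) {
    w <- .pt_chop(w, 2L)
  } else if (.pt_ends(w, "ies")) {
    w <- paste0(.pt_chop(w, 3L), "i")
  } else if (!.pt_ends(w, "ss") && .pt_ends(w, "s")) {
    w <- .pt_chop(w, 1L)
  }

  # step 1b: -eed / -ed / -ing
  restore <- FALSE
  if (.pt_ends(w, "eed")) {
    if (.pt_measure(.pt_chop(w, 3L)) > 0L) w <- .pt_chop(w, 1L)
  } else if (.pt_ends(w, "ed") && .pt_has_vowel(.pt_chop(w, 2L))) {
    w <- .pt_chop(w, 2L)
    restore <- TRUE
  } else if (.pt_ends(w, "ing") && .pt_has_vowel(.pt_chop(w, 3L))) {
    w <- .pt_chop(w, 3L)
    restore <- TRUE
  }
  if (restore) {
    if (.pt_ends(w, "at") || .pt_ends(w, "bl") || .pt_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.pt_double_cons(w) &&
               !(substring(w, nchar(w)) %in% c("l", "s", "z"))) {
      w <- .pt_chop(w, 1L)
    } else if (.pt_measure(w) == 1L && .pt_ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c: terminal y -> i after a vowel-bearing stem
  if (.pt_ends(w, "y") && .pt_has_vowel(.pt_chop(w, 1L))) {
    w <- paste0(.pt_chop(w, 1L), "i")
  }

  # step 2: double-suffix reductions, m > 0
  for (rule in .pt_step2_rules) {
    if (.pt_ends(w, rule[1L])) {
      stem <- .pt_chop(w, nchar(rule[1L]))
      if (.pt_measure(stem) > 0L) w <- paste0(stem, rule[2L])
      break
    }
  }

  # step 3: -ic-, -full, -ness etc., m > 0
  for (rule in .pt_step3_rules) {
    if (.pt_ends(w, rule[1L])) {
      stem <- .pt_chop(w, nchar(rule[1L]))
      if (.pt_measure(stem) > 0L) w <- paste0(stem, rule[2L])
      break
    }
  }

  # step 4: strip residual suffixes when m > 1
  for (suf in .pt_step4_suffixes) {
    if (.pt_ends(w, suf)) {
      stem <- .pt_chop(w, nchar(suf))
      ok <- .pt_measure(stem) > 1L
      if (suf == "ion") {
        ok <- ok && substring(stem, nchar(stem)) %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a: drop a final e
  if (.pt_ends(w, "e")) {
    stem <- .pt_chop(w, 1L)
    m <- .pt_measure(stem)
    if (m > 1L || (m == 1L && !.pt_ends_cvc(stem))) w <- stem
  }

  # step 5b: -ll -> -l for m > 1
  if (.pt_measure(w) > 1L && .pt_double_cons(w) &&
      substring(w, nchar(w)) == "l") {
    w <- .pt_chop(w, 1L)
  }

  w
}
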