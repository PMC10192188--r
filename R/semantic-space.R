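#' Embedding spaces: construction and I/O
#'
#' An `embedding_space` holds one real-valued meaning vector per word,
#' all of the same dimensionality, together with the cosine geometry used
#' throughout the package.  Spaces are usually read from a word2vec-style
#' text file with [read_word_vectors()] or fabricated by
#' [gen_embedding_space()].
#'
#' @param vectors numeric matrix, one row per word; rownames are the
#'   vocabulary.
#' @param lowercase fold the vocabulary to lower case (the package-wide
#'   lookup convention; stimulus words are folded the same way).
#' @return An object of class `embedding_space`: a list with elements
#'   `vectors` (the matrix) and `dim` (vector length).
#' @export
embedding_space <- function(vectors, lowercase = TRUE) {
  if (!is.matrix(vectors) || !is.numeric(vectors))
    stop("`vectors` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(vectors)))
    stop("`vectors` must have words as rownames", call. = FALSE)
  if (lowercase) rownames(vectors) <- tolower(rownames(vectors))
  if (anyDuplicated(rownames(vectors)))
    stop("duplicate words in vocabulary: ",
         paste(unique(rownames(vectors)[duplicated(rownames(vectors))]),
               collapse = ", "), call. = FALSE)
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0))
    stop("all-zero vector(s) for: ",
         paste(rownames(vectors)[norms == 0], collapse = ", "), call. = FALSE)
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("<embedding_space> ", nrow(x$vectors), " words, ",
      x$dim, " dimensions\n", sep = "")
  invisible(x)
}

#' @rdname embedding_space
#' @param space an `embedding_space`.
#' @export
vocabulary <- function(space) rownames(space$vectors)

# Internal: fetch vectors for words, hard error naming unknown words.
space_lookup <- function(space, words, lowercase = TRUE) {
  if (lowercase) words <- tolower(words)
  idx <- match(words, rownames(space$vectors))
  if (anyNA(idx))
    stop("word(s) not in vocabulary: ",
         paste(unique(words[is.na(idx)]), collapse = ", "), call. = FALSE)
  space$vectors[idx, , drop = FALSE]
}

#' Read word vectors in word2vec text format
#'
#' Reads a text file with an optional `"<n> <dim>"` header line and one
#' `word v1 v2 ... v_dim` record per subsequent line (UTF-8; the first
#' whitespace separates the word from its values).  Words are folded to
#' lower case before lookup, matching the package-wide convention for
#' stimulus words.
#'
#' @param path file to read.
#' @param restrict optional character vector: keep only these words.
#'   Requested words absent from the file are reported via a message and
#'   recorded in the `missing` attribute of the result.
#' @param lowercase fold vocabulary (and `restrict`) to lower case.
#' @return An [embedding_space()] with attribute `missing` (character
#'   vector of requested-but-absent words, empty if none).
#' @export
read_word_vectors <- function(path, restrict = NULL, lowercase = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty vector file: ", path, call. = FALSE)
  start <- 1L
  head_tok <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(head_tok) == 2L && !anyNA(suppressWarnings(as.integer(head_tok))))
    start <- 2L
  body <- lines[seq.int(start, length(lines))]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no vector records in: ", path, call. = FALSE)

  toks <- strsplit(trimws(body), "\\s+")
  words <- vapply(toks, `[[`, character(1), 1L)
  if (lowercase) words <- tolower(words)
  if (!is.null(restrict)) {
    want <- if (lowercase) tolower(restrict) else restrict
    keep <- words %in% want
    missing <- setdiff(want, words)
    if (length(missing))
      message("read_word_vectors: ", length(missing),
              " requested word(s) not found: ",
              paste(missing, collapse = ", "))
    toks <- toks[keep]; words <- words[keep]
    if (length(words) == 0L)
      stop("none of the requested words found in: ", path, call. = FALSE)
  } else missing <- character(0)

  dims <- lengths(toks) - 1L
  if (length(unique(dims)) != 1L)
    stop("inconsistent vector dimensionality (", paste(unique(dims),
         collapse = ", "), ") in: ", path, call. = FALSE)
  vals <- suppressWarnings(
    vapply(toks, function(tk) as.numeric(tk[-1L]), numeric(dims[[1L]])))
  if (dims[[1L]] == 1L) vals <- matrix(vals, nrow = 1L)
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1L]
    stop("malformed vector values at data line ", bad, " (word '",
         words[bad], "') in: ", path, call. = FALSE)
  }
  m <- t(vals)
  rownames(m) <- words
  sp <- embedding_space(m, lowercase = FALSE)
  attr(sp, "missing") <- missing
  sp
}

#' @rdname read_word_vectors
#' @param space an `embedding_space` to write.
#' @param header write the `"<n> <dim>"` header line.
#' @export
write_word_vectors <- function(space, path, header = TRUE) {
  m <- space$vectors
  rec <- paste(rownames(m),
               apply(m, 1L, function(v) paste(format(v, digits = 17,
                                                     scientific = FALSE,
                                                     trim = TRUE),
                                              collapse = " ")))
  if (header) rec <- c(paste(nrow(m), ncol(m)), rec)
  writeLines(rec, path, useBytes = TRUE)
  invisible(path)
}

#' Read word-frequency norms
#'
#' Reads a two-column tab-separated file of corpus occurrence counts
#' (columns `word`, `count`), as distributed by the SUBTLEX family of
#' norms.  Counts are kept exactly as stored: the SSim statistic is
#' invariant under rescaling all frequencies by a positive constant, so
#' raw counts, per-million rates and the like are interchangeable.
#'
#' @param path TSV file with columns `word` and `count`.
#' @param lowercase fold words to lower case.
#' @return A named numeric vector of class `freq_norms`.
#' @export
read_frequency_norms <- function(path, lowercase = TRUE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("word", "count") %in% names(d)))
    stop("frequency file needs columns `word` and `count`: ", path,
         call. = FALSE)
  freq_norms(stats::setNames(as.numeric(d$count), d$word),
             lowercase = lowercase)
}

#' @rdname read_frequency_norms
#' @param counts named numeric vector of nonnegative counts.
#' @export
freq_norms <- function(counts, lowercase = TRUE) {
  if (is.null(names(counts)) || !is.numeric(counts))
    stop("`counts` must be a named numeric vector", call. = FALSE)
  if (lowercase) names(counts) <- tolower(names(counts))
  if (any(counts < 0) || anyNA(counts))
    stop("frequency counts must be nonnegative and non-missing",
         call. = FALSE)
  structure(counts, class = "freq_norms")
}

#' @rdname read_frequency_norms
#' @param freqs a `freq_norms` object.
#' @param words words to look up; an unknown word is an error, never a
#'   silent zero.
#' @export
freq_of <- function(freqs, words, lowercase = TRUE) {
  if (lowercase) words <- tolower(words)
  idx <- match(words, names(freqs))
  if (anyNA(idx))
    stop("word(s) not in frequency norms: ",
         paste(unique(words[is.na(idx)]), collapse = ", "), call. = FALSE)
  unname(unclass(freqs)[idx])
}

#' @rdname read_frequency_norms
#' @export
write_frequency_norms <- function(freqs, path) {
  utils::write.table(data.frame(word = names(freqs),
                                count = as.numeric(freqs)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cosine similarity between two words
#'
#' The cosine of the angle between the two meaning vectors,
#' `dot(a, b) / (|a| |b|)`; higher values indicate more semantically
#' similar words.
#'
#' @param a,b words (must be in the vocabulary).
#' @param space an [embedding_space()].
#' @return A number in `[-1, 1]`, symmetric in its arguments.
#' @export
cosine_sim <- function(a, b, space) {
  va <- space_lookup(space, a)[1L, ]
  vb <- space_lookup(space, b)[1L, ]
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Matrix of pairwise cosines
#'
#' @param words character vector of vocabulary words.
#' @param space an [embedding_space()].
#' @return A symmetric matrix with unit diagonal, dimnames `words`.
#' @export
cosine_matrix <- function(words, space) {
  v <- space_lookup(space, words)
  v <- v / sqrt(rowSums(v^2))
  m <- tcrossprod(v)
  m <- (m + t(m)) / 2          # enforce exact symmetry against fp noise
  diag(m) <- 1
  dimnames(m) <- list(words, words)
  m
}

#' Frequency-weighted semantic similarity (SSim)
#'
#' The SSim index for a recognition probe is the frequency-weighted mean
#' of the cosines between the probe's vector and the vectors of its
#' list's studied words:
#' \deqn{SSim(nw) = \frac{\sum_i \cos(nw, sw_i)\, F(sw_i)}
#'                       {\sum_i F(sw_i)}}
#' where the weights `F` are corpus occurrence counts.  Being a convex
#' combination, SSim is bounded by the smallest and largest cosine
#' entering the sum, and it is invariant under rescaling all frequencies
#' by a positive constant.
#'
#' @param probe a word.
#' @param context the studied words it is scored against (12 for new
#'   probes; the 11 other list members for a studied probe).
#' @param space an [embedding_space()].
#' @param freqs a [freq_norms()] object.
#' @param skip_oov drop context words missing from the space or norms
#'   from the weighted sum (with a message) instead of erroring.
#' @return The SSim value, a number in `[-1, 1]`.
#' @export
ssim <- function(probe, context, space, freqs, skip_oov = FALSE) {
  if (length(context) == 0L) stop("empty context", call. = FALSE)
  if (skip_oov) {
    known <- tolower(context) %in% vocabulary(space) &
      tolower(context) %in% names(freqs)
    if (!all(known)) {
      message("ssim: skipping out-of-vocabulary word(s): ",
              paste(context[!known], collapse = ", "))
      context <- context[known]
    }
    if (length(context) == 0L)
      stop("all context words out of vocabulary", call. = FALSE)
  }
  vp <- space_lookup(space, probe)[1L, ]
  vc <- space_lookup(space, context)
  cosines <- as.vector(vc %*% vp) /
    (sqrt(rowSums(vc^2)) * sqrt(sum(vp^2)))
  w <- freq_of(freqs, context)
  if (sum(w) <= 0)
    stop("degenerate weights: total frequency mass is zero", call. = FALSE)
  sum(cosines * w) / sum(w)
}

#' Study-list definitions
#'
#' A `study_lists` object is a data frame with one row per stimulus word
#' and columns `list_id`, `role` (one of `studied`, `critical_lure`,
#' `weak_lure`, `unrelated`), `position` (1-based study order for
#' studied words, `NA` otherwise) and `word`.  Unrelated words carry the
#' `list_id` of the list they were randomly matched with for scoring.
#'
#' @param df data frame with the four columns above.
#' @param words_per_list number of studied words per list.
#' @return The validated data frame with class `study_lists`.
#' @export
study_lists <- function(df, words_per_list = 12L) {
  need <- c("list_id", "role", "position", "word")
  if (!all(need %in% names(df)))
    stop("study lists need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ok_roles <- c("studied", "critical_lure", "weak_lure", "unrelated")
  if (!all(df$role %in% ok_roles))
    stop("unknown role(s): ",
         paste(setdiff(df$role, ok_roles), collapse = ", "), call. = FALSE)
  for (lid in unique(df$list_id)) {
    st <- df$word[df$list_id == lid & df$role == "studied"]
    if (length(st) != words_per_list || anyDuplicated(st))
      stop("list ", lid, ": expected ", words_per_list,
           " distinct studied words, got ", length(st), call. = FALSE)
    lures <- df$word[df$list_id == lid &
                       df$role %in% c("critical_lure", "weak_lure")]
    if (any(lures %in% st))
      stop("list ", lid, ": lure word(s) also in studied set: ",
           paste(intersect(lures, st), collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)
  class(df) <- c("study_lists", "data.frame")
  df
}

#' @rdname study_lists
#' @param path CSV file with columns `list_id`, `role`, `position`, `word`.
#' @export
read_study_lists <- function(path, words_per_list = 12L) {
  study_lists(utils::read.csv(path, stringsAsFactors = FALSE),
              words_per_list = words_per_list)
}

#' @rdname study_lists
#' @param lists a `study_lists` object.
#' @export
write_study_lists <- function(lists, path) {
  utils::write.csv(as.data.frame(lists), path, row.names = FALSE)
  invisible(path)
}

#' Score every recognition item with SSim
#'
#' New words (critical lures, weak lures, unrelated words) are scored
#' against all studied words of their (assigned) list; each studied word
#' is scored against the other list members, the self term excluded.
#'
#' @param lists a [study_lists()] object.
#' @param space an [embedding_space()].
#' @param freqs a [freq_norms()] object.
#' @param skip_oov passed to [ssim()].
#' @return Data frame with columns `word`, `list_id`, `role`, `ssim`.
#' @export
score_items <- function(lists, space, freqs, skip_oov = FALSE) {
  df <- as.data.frame(lists)
  res <- lapply(seq_len(nrow(df)), function(i) {
    w <- df$word[i]; lid <- df$list_id[i]; role <- df$role[i]
    studied <- df$word[df$list_id == lid & df$role == "studied"]
    ctx <- if (role == "studied") setdiff(studied, w) else studied
    val <- tryCatch(ssim(w, ctx, space, freqs, skip_oov = skip_oov),
                    error = function(e)
                      stop("scoring '", w, "' (list ", lid, "): ",
                           conditionMessage(e), call. = FALSE))
    data.frame(word = w, list_id = lid, role = role, ssim = val)
  })
  do.call(rbind, res)
}

#' @rdname score_items
#' @param scores data frame returned by `score_items()`.
#' @param path output CSV path.
#' @export
write_ssim_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
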