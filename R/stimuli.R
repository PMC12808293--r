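#' Rule-plus-exception category structures
#'
#' Builds the binary-feature category structure used in rule-plus-exception
#' category-learning designs: two prototypes (`000...0` for category A,
#' `111...1` for category B), one-feature variants ("typicals") of each
#' prototype, and optional "exception" items that belong to one category but
#' lie at Hamming distance 1 from the *opposite* category's prototype (and
#' hence distance `n_features - 1` from their own).
#'
#' The assignment of flipped dimensions is deterministic so that a structure
#' is reproducible bit-for-bit. Exceptions take dimensions from the top,
#' alternating between categories (category A's exception flips dimension
#' `M - 1` of the B prototype, category B's flips dimension `M` of the A
#' prototype); each category's typicals flip every dimension not used by the
#' *opposite* category's exceptions. Two consequences matter: (1) feature
#' vectors stay unique, and (2) each exception's distinguishing dimension is
#' shared with one of its own category's typicals, so a prototype model
#' cannot re-weight attention to classify an exception correctly without
#' misclassifying a typical — the structure keeps the two model families
#' distinguishable. Requests for exception counts that would force duplicate
#' feature vectors are rejected.
#'
#' @param n_features Number of binary feature dimensions `M` (default 6).
#' @param n_exceptions_per_category Number of exception items per category
#'   (default 1).
#' @return An object of class `category_structure`: a list with elements
#'   `stimuli` (data frame with columns `id`, feature columns `f1..fM`,
#'   `category`, `role`, `word`), `n_features`, `n_exceptions_per_category`,
#'   and `prototypes` (2 x M matrix, rows A and B).
#' @examples
#' cs <- make_rule_plus_exception()
#' table(cs$stimuli$role)
#' @export
make_rule_plus_exception <- function(n_features = 6L, n_exceptions_per_category = 1L) {
  M <- as.integer(n_features)
  k <- as.integer(n_exceptions_per_category)
  if (is.na(M) || M < 2L) stop("n_features must be an integer >= 2")
  if (is.na(k) || k < 0L || k > M - 1L)
    stop("n_exceptions_per_category must be in 0..(n_features - 1)")

  # exception dimensions, highest first, alternating B (even offsets) / A (odd):
  # for k = 1, M = 6 this is A -> dim 5, B -> dim 6
  exc_dims_A <- if (k > 0L) M - seq.int(1L, by = 2L, length.out = k) else integer(0)
  exc_dims_B <- if (k > 0L) M - seq.int(0L, by = 2L, length.out = k) else integer(0)
  if (k > 0L && min(c(exc_dims_A, exc_dims_B)) < 1L)
    stop("n_exceptions_per_category = ", k, " needs more dimensions than available")
  # typicals avoid the opposite category's exception dimensions (uniqueness)
  typ_dims_A <- setdiff(seq_len(M), exc_dims_B)
  typ_dims_B <- setdiff(seq_len(M), exc_dims_A)
  if (length(typ_dims_A) < M - 1L || length(typ_dims_B) < M - 1L)
    stop("n_exceptions_per_category = ", k,
         " forces duplicate feature vectors (typicals need ", M - 1L,
         " free dimensions)")
  typ_dims_A <- typ_dims_A[seq_len(M - 1L)]
  typ_dims_B <- typ_dims_B[seq_len(M - 1L)]

  proto_A <- rep(0L, M)
  proto_B <- rep(1L, M)
  flip <- function(v, dim) { v[dim] <- 1L - v[dim]; v }

  rows <- list()
  add <- function(features, category, role) {
    rows[[length(rows) + 1L]] <<- list(features = features, category = category, role = role)
  }
  for (cat in c("A", "B")) {
    own <- if (cat == "A") proto_A else proto_B
    other <- if (cat == "A") proto_B else proto_A
    typ_dims <- if (cat == "A") typ_dims_A else typ_dims_B
    exc_dims <- if (cat == "A") exc_dims_A else exc_dims_B
    add(own, cat, "prototype")
    for (d in typ_dims) add(flip(own, d), cat, "typical")
    for (d in exc_dims) add(flip(other, d), cat, "exception")
  }

  feats <- do.call(rbind, lapply(rows, `[[`, "features"))
  if (anyDuplicated(apply(feats, 1L, paste, collapse = "")))
    stop("internal error: duplicate feature vectors generated")

  stimuli <- data.frame(id = seq_along(rows))
  colnames(feats) <- paste0("f", seq_len(M))
  stimuli <- cbind(stimuli, as.data.frame(feats))
  stimuli$category <- vapply(rows, `[[`, "", "category")
  stimuli$role <- vapply(rows, `[[`, "", "role")
  stimuli$word <- NA_character_

  prototypes <- rbind(A = proto_A, B = proto_B)
  structure(
    list(stimuli = stimuli, n_features = M,
         n_exceptions_per_category = k, prototypes = prototypes),
    class = "category_structure"
  )
}

#' @export
print.category_structure <- function(x, ...) {
  cat(sprintf("Rule-plus-exception category structure: %d stimuli, %d features, %d exception(s)/category\n",
              nrow(x$stimuli), x$n_features, x$n_exceptions_per_category))
  print(x$stimuli, row.names = FALSE)
  invisible(x)
}

#' Feature matrix of a category structure
#'
#' @param structure A `category_structure`.
#' @return Integer matrix (stimuli x features); rows ordered by stimulus id.
#' @export
feature_matrix <- function(structure) {
  stopifnot(inherits(structure, "category_structure"))
  as.matrix(structure$stimuli[paste0("f", seq_len(structure$n_features))])
}

#' Default letter table for nonsense-word rendering
#'
#' A 6 x 2 table of letters, one row per feature dimension, alternating
#' consonant and vowel positions, under which the two prototypes render to
#' "gafuzi" and "livamo".
#'
#' @return Character matrix with one row per dimension and columns `0`, `1`.
#' @export
default_letter_table <- function() {
  m <- rbind(c("g", "l"), c("a", "i"), c("f", "v"),
             c("u", "a"), c("z", "m"), c("i", "o"))
  colnames(m) <- c("0", "1")
  m
}

#' Render stimuli as nonsense words
#'
#' Fills the `word` field of each stimulus: the m-th letter of a word is
#' `letter_table[m, features[m] + 1]`. Rendering is cosmetic; all models
#' operate on feature vectors.
#'
#' @param structure A `category_structure`.
#' @param letter_table Character matrix with `n_features` rows and 2 columns
#'   (letters for feature values 0 and 1). Rows must alternate
#'   consonant/vowel positions and hold two distinct letters each.
#' @return The structure with `word` fields populated.
#' @examples
#' cs <- render_words(make_rule_plus_exception())
#' cs$stimuli$word[cs$stimuli$role == "prototype"]
#' @export
render_words <- function(structure, letter_table = default_letter_table()) {
  stopifnot(inherits(structure, "category_structure"))
  lt <- as.matrix(letter_table)
  M <- structure$n_features
  if (nrow(lt) != M || ncol(lt) != 2L)
    stop("letter_table must have n_features rows and 2 columns")
  if (!all(nchar(lt) == 1L)) stop("letter_table entries must be single letters")
  same <- lt[, 1L] == lt[, 2L]
  if (any(same)) stop("letter_table rows must hold two distinct letters")
  vowels <- c("a", "e", "i", "o", "u")
  is_vowel_row <- apply(lt, 1L, function(r) all(tolower(r) %in% vowels))
  is_cons_row <- apply(lt, 1L, function(r) !any(tolower(r) %in% vowels))
  expect_vowel <- (seq_len(M) %% 2L) == 0L   # positions 2, 4, ... are vowels
  if (!all(ifelse(expect_vowel, is_vowel_row, is_cons_row)))
    stop("letter_table rows must alternate consonant/vowel positions")

  feats <- feature_matrix(structure)
  structure$stimuli$word <- apply(feats, 1L, function(f)
    paste(lt[cbind(seq_len(M), f + 1L)], collapse = ""))
  structure
}

#' Pairwise Hamming distances between stimuli
#'
#' @param structure A `category_structure`.
#' @return Symmetric integer matrix of Hamming distances (zero diagonal).
#' @export
hamming_matrix <- function(structure) {
  feats <- feature_matrix(structure)
  n <- nrow(feats)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) d[i, ] <- as.integer(colSums(abs(t(feats) - feats[i, ])))
  dimnames(d) <- list(structure$stimuli$id, structure$stimuli$id)
  d
}

#' Export / import a category structure as CSV
#'
#' The CSV schema is one row per stimulus: `id`, feature columns `f1..fM`,
#' `category`, `role`, `word`.
#'
#' @param structure A `category_structure`.
#' @param path File path.
#' @return `write_structure_csv` returns `path` invisibly;
#'   `read_structure_csv` returns a `category_structure`.
#' @export
write_structure_csv <- function(structure, path) {
  stopifnot(inherits(structure, "category_structure"))
  utils::write.csv(structure$stimuli, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_structure_csv
#' @export
read_structure_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  M <- length(fcols)
  if (M < 2L) stop("no feature columns f1..fM found in ", path)
  df$word <- if ("word" %in% names(df)) as.character(df$word) else NA_character_
  k <- sum(df$role == "exception" & df$category == "A")
  prototypes <- rbind(A = rep(0L, M), B = rep(1L, M))
  structure(
    list(stimuli = df[c("id", fcols, "category", "role", "word")],
         n_features = M, n_exceptions_per_category = k, prototypes = prototypes),
    class = "category_structure"
  )
}

#' Export / import a category structure as a YAML config
#'
#' @inheritParams write_structure_csv
#' @return `write_structure_yaml` returns `path` invisibly;
#'   `read_structure_yaml` rebuilds the structure from the stored
#'   construction arguments (the structure itself is deterministic).
#' @export
write_structure_yaml <- function(structure, path) {
  stopifnot(inherits(structure, "category_structure"))
  yaml::write_yaml(list(
    n_features = structure$n_features,
    n_exceptions_per_category = structure$n_exceptions_per_category
  ), path)
  invisible(path)
}

#' @rdname write_structure_yaml
#' @export
read_structure_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  make_rule_plus_exception(cfg$n_features, cfg$n_exceptions_per_category)
}
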