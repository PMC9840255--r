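#' Toy chemistry worlds
#'
#' A toy world is a closed, fully enumerable stand-in for a real reaction
#' corpus: molecules are non-empty strings over a small alphabet, reaction
#' templates rewrite a contiguous pattern into two strictly simpler precursor
#' fragments, and a stock set lists the "purchasable" strings. Because
#' templates strictly simplify, every retrosynthetic route terminates and a
#' brute-force oracle can compute the exact minimal synthesis depth of any
#' molecule. That ground truth is what the assessment layer is calibrated
#' against.
#'
#' @name toyworld
NULL

toy_alphabet <- function(n) letters[seq_len(n)]

random_string <- function(alphabet, len) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Construct a toy world
#'
#' Validates the structural invariants: templates must strictly simplify
#' (each precursor fragment is non-empty and shorter than the pattern it
#' replaces, so every precursor molecule is strictly shorter than the
#' product), and the stock is a non-empty duplicate-free set of molecules
#' over the alphabet.
#'
#' @param alphabet_size number of distinct symbols (letters), at least 2.
#' @param templates list of templates, each a list with `template_id`
#'   (integer), `pattern` (string, length >= 2) and `parts` (character
#'   vector of 2 precursor fragments).
#' @param stock character vector of in-stock molecules.
#' @param seed integer seed the world was generated from (`NA` for
#'   hand-built worlds).
#' @return an object of class `toy_world`.
#' @seealso [generate_world()] for sampling worlds.
#' @export
toy_world <- function(alphabet_size, templates, stock, seed = NA_integer_) {
  alphabet_size <- as.integer(alphabet_size)
  if (is.na(alphabet_size) || alphabet_size < 2L)
    stop("alphabet_size must be an integer >= 2")
  ab <- toy_alphabet(alphabet_size)
  if (!is.list(templates) || length(templates) == 0L)
    stop("templates must be a non-empty list")
  ok_chars <- function(s) all(strsplit(s, "")[[1]] %in% ab)
  for (tpl in templates) {
    if (!all(c("template_id", "pattern", "parts") %in% names(tpl)))
      stop("each template needs template_id, pattern and parts")
    L <- nchar(tpl$pattern)
    if (L < 2L) stop("template pattern must have length >= 2")
    if (length(tpl$parts) != 2L) stop("template must have exactly 2 parts")
    pl <- nchar(tpl$parts)
    if (any(pl < 1L) || any(pl > L - 1L))
      stop("template parts must be non-empty and shorter than the pattern")
    if (sum(pl) < L - 1L)
      stop("template parts must jointly keep complexity >= pattern length - 1")
    if (!ok_chars(tpl$pattern) || !all(vapply(tpl$parts, ok_chars, logical(1))))
      stop("template symbols outside the alphabet")
  }
  ids <- vapply(templates, function(t) as.integer(t$template_id), integer(1))
  if (anyDuplicated(ids)) stop("template ids must be unique")
  stock <- as.character(stock)
  if (length(stock) == 0L) stop("stock must be non-empty")
  if (anyDuplicated(stock)) stop("stock must be duplicate-free")
  if (any(nchar(stock) < 1L) || !all(vapply(stock, ok_chars, logical(1))))
    stop("stock molecules must be non-empty strings over the alphabet")
  structure(
    list(alphabet_size = alphabet_size, alphabet = ab,
         templates = templates[order(ids)], stock = stock,
         seed = as.integer(seed)),
    class = "toy_world")
}

#' @export
print.toy_world <- function(x, ...) {
  cat(sprintf("toy_world: alphabet %d, %d templates, %d stock molecules (seed %s)\n",
              x$alphabet_size, length(x$templates), length(x$stock),
              ifelse(is.na(x$seed), "none", x$seed)))
  invisible(x)
}

#' Generate a random toy world
#'
#' Samples a stock of purchasable molecules first and then a set of rewrite
#' templates. Templates and stock are sampled independently, so generated
#' target molecules can be genuinely unsynthesizable — the assessment layer
#' needs both classes. Patterns have length 2 or 3 and each precursor
#' fragment is non-empty and shorter than the pattern, which makes every
#' template strictly simplifying and every search depth-bounded.
#'
#' The world is a pure function of its arguments: the same call returns a
#' field-by-field identical world.
#'
#' @param alphabet_size number of symbols, >= 2.
#' @param n_templates number of distinct templates, >= 1.
#' @param stock_size number of distinct stock molecules, >= 1.
#' @param stock_max_len maximal stock molecule length (default 3).
#' @param seed integer RNG seed; the only randomness source.
#' @return a [toy_world()] object.
#' @export
generate_world <- function(alphabet_size, n_templates, stock_size,
                           stock_max_len = 3L, seed = 1L) {
  if (alphabet_size < 2L) stop("alphabet_size must be >= 2")
  if (n_templates < 1L) stop("n_templates must be >= 1")
  if (stock_size < 1L) stop("stock_size must be >= 1")
  if (stock_max_len < 1L) stop("stock_max_len must be >= 1")
  n_avail <- sum(alphabet_size^seq_len(stock_max_len))
  if (stock_size > n_avail)
    stop("stock_size exceeds the number of distinct molecules of that length")
  withr::with_seed(as.integer(seed), {
    ab <- toy_alphabet(alphabet_size)
    stock <- character(0)
    attempts <- 0L
    while (length(stock) < stock_size) {
      attempts <- attempts + 1L
      if (attempts > 1000L * stock_size) stop("failed to sample a distinct stock")
      len <- sample.int(stock_max_len, 1L)
      stock <- unique(c(stock, random_string(ab, len)))
    }
    templates <- vector("list", 0L)
    seen <- character(0)
    attempts <- 0L
    while (length(templates) < n_templates) {
      attempts <- attempts + 1L
      if (attempts > 1000L * n_templates) stop("template space exhausted")
      L <- sample(2:3, 1L)
      pattern <- random_string(ab, L)
      if (L == 2L) {
        lens <- c(1L, 1L)
      } else {
        lens <- c(sample(1:2, 1L), sample(1:2, 1L))
      }
      parts <- c(random_string(ab, lens[1]), random_string(ab, lens[2]))
      key <- paste(pattern, parts[1], parts[2])
      if (key %in% seen) next
      seen <- c(seen, key)
      templates[[length(templates) + 1L]] <-
        list(template_id = length(templates) + 1L, pattern = pattern,
             parts = parts)
    }
    toy_world(alphabet_size, templates, sort(stock), seed = seed)
  })
}

#' Apply all reaction templates to a molecule
#'
#' Enumerates every (template, match position) pair. A template with pattern
#' `P` matching molecule `left P right` yields two precursors: the molecule's
#' left context glued to the template's first fragment, and the second
#' fragment glued to the right context. Matches may overlap. The result is
#' ordered by template id, then match position, so expansion is
#' bit-deterministic.
#'
#' @param world a [toy_world()].
#' @param molecule molecule string.
#' @return list of `list(template_id, position, precursors)`; empty when no
#'   template matches.
#' @export
apply_templates <- function(world, molecule) {
  stopifnot(is.character(molecule), length(molecule) == 1L, nchar(molecule) >= 1L)
  out <- list()
  n <- nchar(molecule)
  for (tpl in world$templates) {
    L <- nchar(tpl$pattern)
    if (L > n) next
    for (pos in seq_len(n - L + 1L)) {
      if (substr(molecule, pos, pos + L - 1L) == tpl$pattern) {
        left <- substr(molecule, 1L, pos - 1L)
        right <- substr(molecule, pos + L, n)
        out[[length(out) + 1L]] <- list(
          template_id = tpl$template_id, position = pos,
          precursors = c(paste0(left, tpl$parts[1]),
                         paste0(tpl$parts[2], right)))
      }
    }
  }
  out
}

# Exact minimal synthesis depth, uncapped. Templates strictly simplify, so
# recursion on ever-shorter strings terminates; memoised per molecule.
min_depth_uncapped <- function(world, molecule, memo) {
  if (exists(molecule, envir = memo, inherits = FALSE))
    return(get(molecule, envir = memo, inherits = FALSE))
  if (molecule %in% world$stock) {
    assign(molecule, 0, envir = memo)
    return(0)
  }
  apps <- apply_templates(world, molecule)
  best <- Inf
  for (a in apps) {
    d <- 1 + max(min_depth_uncapped(world, a$precursors[1], memo),
                 min_depth_uncapped(world, a$precursors[2], memo))
    if (d < best) best <- d
  }
  assign(molecule, best, envir = memo)
  best
}

#' Brute-force synthesizability oracle
#'
#' Exhaustively searches all template applications and returns the minimal
#' synthesis depth of a molecule: 0 for stock molecules, otherwise
#' `1 + min over applicable reactions of the deeper of the two precursor
#' depths` — the same longest-branch depth semantics the planner uses. A
#' molecule with no full route of depth at most `max_depth` is reported
#' unsynthesizable.
#'
#' @param world a [toy_world()].
#' @param molecule molecule string.
#' @param max_depth depth cap defining "within limit" (default 6, the
#'   planner's default transform limit).
#' @param memo optional environment for memoisation across calls on the same
#'   world.
#' @return list of class `oracle_result` with `min_depth` (integer, `NA`
#'   when unsynthesizable within the cap), `within_limit` and
#'   `unsynthesizable` (logicals).
#' @export
oracle_min_depth <- function(world, molecule, max_depth = 6L, memo = NULL) {
  if (max_depth < 0L) stop("max_depth must be >= 0")
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  d <- min_depth_uncapped(world, molecule, memo)
  unsyn <- is.infinite(d) || d > max_depth
  structure(
    list(min_depth = if (unsyn) NA_integer_ else as.integer(d),
         within_limit = !unsyn, unsynthesizable = unsyn),
    class = "oracle_result")
}

#' Ideal synthetic-accessibility score from the oracle
#'
#' Maps the oracle's minimal depth to the unit interval:
#' `max(0, 1 - min_depth / (max_depth + 1))`, and 0 for molecules
#' unsynthesizable within the cap. Stock molecules score exactly 1 and the
#' score is strictly decreasing in minimal depth, so it is the best-informed
#' score any method could produce on a toy world — the positive control for
#' score recovery experiments.
#'
#' @inheritParams oracle_min_depth
#' @return value in `[0, 1]`.
#' @export
oracle_score <- function(world, molecule, max_depth = 6L, memo = NULL) {
  res <- oracle_min_depth(world, molecule, max_depth = max_depth, memo = memo)
  if (!res$within_limit) return(0)
  max(0, 1 - res$min_depth / (max_depth + 1))
}

#' Pure-noise score (negative control)
#'
#' Deterministic per (molecule, seed) and marginally uniform on `[0, 1]`
#' over random molecules: a hash of the molecule string seeds an isolated
#' RNG draw, so repeated calls agree and the global RNG state is untouched.
#' Used as the uninformative control against which chance-level
#' discrimination is checked.
#'
#' @param molecule molecule string.
#' @param seed integer stream seed.
#' @return value in `[0, 1]`.
#' @export
noise_score <- function(molecule, seed = 1L) {
  stopifnot(is.character(molecule), length(molecule) == 1L, !is.na(molecule))
  codes <- utf8ToInt(molecule)
  h <- as.numeric(seed) %% 2147483647
  for (cd in codes) h <- (h * 31 + cd) %% 2147483647
  h <- (h * 69069 + 1) %% 2147483647
  withr::with_seed(as.integer(h), stats::runif(1L))
}
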