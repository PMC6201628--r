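# Readers and writers for the plain-text artifacts the pipeline touches:
# edge lists (TSV / SIF), RNK ranked profiles, GMT extreme signatures,
# herb-library and contraindication tables. UTF-8, LF, '#' comments.

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

.is_comment <- function(lines) grepl("^\\s*(#|$)", lines)

#' Read a network edge list (two-column TSV or SIF)
#'
#' Accepts two whitespace/tab-separated columns per line, or the SIF dialect
#' `node relation node` from which columns 1 and 3 are taken. Lines starting
#' with `#` and blank lines are skipped.
#'
#' @param path Path to the edge-list file.
#' @return A two-column character matrix of gene pairs.
#' @export
read_network_edges <- function(path) {
  lines <- .read_lines(path)
  keep <- which(!.is_comment(lines))
  tokens <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(vapply(tokens, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge line ", keep[bad[1L]], ": '", lines[keep[bad[1L]]], "'")
  }
  pairs <- t(vapply(tokens, function(tk) {
    if (length(tk) >= 3L) c(tk[1L], tk[3L]) else tk[1:2]
  }, character(2)))
  colnames(pairs) <- c("from", "to")
  pairs
}

#' Write a network edge list as TSV
#' @param edges Two-column character matrix or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a ranked disease profile
#'
#' A disease-pathological state profile: unique genes ordered by descending
#' fold change, most up-regulated first. Ties are broken by ascending gene
#' symbol (C-locale radix order) so the ranking is deterministic across
#' platforms.
#'
#' @param genes Character vector of unique gene symbols.
#' @param values Numeric fold-change values, same length.
#' @param id Optional profile identifier.
#' @return An object of class `ranked_profile`: a data frame with columns
#'   `gene` and `value`, sorted, plus attribute `id`.
#' @export
ranked_profile <- function(genes, values, id = NULL) {
  genes <- as.character(genes)
  if (length(genes) != length(values)) stop("genes and values differ in length")
  if (anyDuplicated(genes)) {
    stop("duplicate gene(s) in profile: ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5L), collapse = ", "))
  }
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite fold-change value(s) in profile")
  ord <- order(-values, genes, method = "radix")
  out <- data.frame(gene = genes[ord], value = values[ord])
  class(out) <- c("ranked_profile", "data.frame")
  attr(out, "id") <- id
  out
}

#' @export
print.ranked_profile <- function(x, ...) {
  id <- attr(x, "id")
  cat("Ranked disease profile", if (!is.null(id)) paste0("'", id, "'"),
      "with", nrow(x), "genes\n")
  print.data.frame(utils::head(x, 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Read an RNK-style ranked profile
#'
#' Two tab/whitespace-separated columns: gene symbol and numeric fold change.
#' Rows are re-sorted into canonical order (descending value, ties by
#' ascending gene symbol). Duplicate genes and non-numeric values are errors.
#'
#' @param path Path to the RNK file.
#' @param id Optional profile identifier (defaults to the file name).
#' @return A [ranked_profile()].
#' @export
read_ranked_profile <- function(path, id = NULL) {
  lines <- .read_lines(path)
  keep <- which(!.is_comment(lines))
  tokens <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(vapply(tokens, length, integer(1)) < 2L)
  if (length(bad) > 0L) stop("malformed profile line ", keep[bad[1L]])
  genes <- vapply(tokens, `[[`, character(1), 1L)
  raw <- vapply(tokens, `[[`, character(1), 2L)
  values <- suppressWarnings(as.numeric(raw))
  if (any(is.na(values))) {
    stop("non-numeric fold change on line ", keep[which(is.na(values))[1L]],
         ": '", raw[which(is.na(values))[1L]], "'")
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  ranked_profile(genes, values, id = id)
}

#' Write a ranked profile as RNK
#' @param profile A [ranked_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_profile <- function(profile, path) {
  utils::write.table(profile[, c("gene", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a herb library table
#'
#' Expects a TSV with a header naming (at least) the columns `herb_id`,
#' `ingredient_id`, `target_gene`, `mode` and optionally `content`. `mode`
#' must be +1 (target activated by the ingredient) or -1 (inhibited).
#' `content` is the ingredient's content fraction in (0, 1]; when the column
#' holds unambiguously percent-style values (some value > 10, none above
#' 100) the whole column is divided by 100 with a warning; values barely
#' above 1 are rejected as out of range rather than silently rescaled. Missing content is kept as `NA`
#' and treated as weight 1 downstream.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `herb_id`, `ingredient_id`,
#'   `target_gene`, `mode`, `content`.
#' @export
read_herb_library <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("herb_id", "ingredient_id", "target_gene", "mode")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("herb library missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"content" %in% names(df)) df$content <- NA_real_
  validate_herb_library(df)
}

#' Validate (and canonicalise) a herb library table
#' @param df Data frame with herb-library columns.
#' @return The validated data frame.
#' @export
validate_herb_library <- function(df) {
  df$herb_id <- as.character(df$herb_id)
  df$ingredient_id <- as.character(df$ingredient_id)
  df$target_gene <- as.character(df$target_gene)
  df$mode <- suppressWarnings(as.numeric(df$mode))
  if (any(is.na(df$mode)) || !all(df$mode %in% c(-1, 1))) {
    stop("herb library 'mode' must be +1 or -1")
  }
  df$mode <- as.integer(df$mode)
  df$content <- suppressWarnings(as.numeric(df$content))
  known <- !is.na(df$content)
  if (any(known)) {
    # a fraction column never exceeds 1; rescale only when the values are
    # unambiguously percent-scale (some value > 10, none above 100)
    if (any(df$content[known] > 10) && all(df$content[known] <= 100)) {
      warning("content column looks percent-scaled; dividing by 100")
      df$content[known] <- df$content[known] / 100
    }
    if (any(df$content[known] <= 0 | df$content[known] > 1)) {
      stop("herb library 'content' must lie in (0, 1]")
    }
  }
  key <- paste(df$herb_id, df$ingredient_id, df$target_gene, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (herb, ingredient, target) row(s), first: ",
         gsub("\r", " / ", key[duplicated(key)][1L]))
  }
  rownames(df) <- NULL
  df
}

#' Write a herb library table as TSV
#' @param df Herb library data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_herb_library <- function(df, path) {
  out <- df
  out$content <- ifelse(is.na(out$content), "", format(out$content, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a contraindication set
#'
#' Unordered herb-id pairs that no candidate combination may contain.
#' Self-pairs are rejected; lookup is symmetric.
#'
#' @param pairs Two-column character matrix or data frame of herb-id pairs,
#'   or `NULL` for an empty set.
#' @return An object of class `contraindication_set`.
#' @export
contraindication_set <- function(pairs = NULL) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    keys <- character(0)
    mat <- matrix(character(0), ncol = 2L)
  } else {
    if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
    a <- as.character(pairs[, 1L])
    b <- as.character(pairs[, 2L])
    if (any(a == b)) stop("contraindication self-pair: ", a[a == b][1L])
    keys <- unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
    mat <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  }
  structure(list(keys = keys, pairs = mat), class = "contraindication_set")
}

#' Read contraindication pairs from a two-column TSV
#' @param path Path to the file ('#' comments allowed, optional header
#'   starting with 'herb').
#' @return A [contraindication_set()].
#' @export
read_contraindications <- function(path) {
  lines <- .read_lines(path)
  keep <- which(!.is_comment(lines) & !grepl("^herb", lines, ignore.case = TRUE))
  if (length(keep) == 0L) return(contraindication_set(NULL))
  tokens <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(vapply(tokens, length, integer(1)) < 2L)
  if (length(bad) > 0L) stop("malformed contraindication line ", keep[bad[1L]])
  contraindication_set(t(vapply(tokens, function(tk) tk[1:2], character(2))))
}

#' Test whether two herbs are contraindicated
#' @param contra A [contraindication_set()].
#' @param a,b Herb ids (vectorised over pairs).
#' @return Logical.
#' @export
is_contraindicated <- function(contra, a, b) {
  if (is.null(contra)) return(rep(FALSE, length(a)))
  paste(pmin(a, b), pmax(a, b), sep = "\r") %in% contra$keys
}

# Any contraindicated pair within one herb set?
.violates_contra <- function(herbs, contra) {
  if (is.null(contra) || length(contra$keys) == 0L || length(herbs) < 2L) {
    return(FALSE)
  }
  cmb <- utils::combn(sort(herbs), 2L)
  any(paste(cmb[1L, ], cmb[2L, ], sep = "\r") %in% contra$keys)
}

#' Write extreme signatures to a GMT file
#'
#' One line per gene set in standard GMT layout (name, description, genes).
#' Each signature contributes two lines named `<id>__top` and `<id>__bottom`.
#' An empty signature list yields an empty file.
#'
#' @param signatures List of [extreme_signature()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_gmt <- function(signatures, path) {
  lines <- character(0)
  for (sig in signatures) {
    stopifnot(inherits(sig, "extreme_signature"))
    if (grepl("\t", sig$id, fixed = TRUE)) {
      stop("signature id contains a tab: ", sig$id)
    }
    lines <- c(
      lines,
      paste(c(paste0(sig$id, "__top"), "na", sig$top), collapse = "\t"),
      paste(c(paste0(sig$id, "__bottom"), "na", sig$bottom), collapse = "\t")
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read extreme signatures from a GMT file written by [write_signature_gmt()]
#' @param path Path to the GMT file.
#' @return Named list of `extreme_signature` objects.
#' @export
read_signature_gmt <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  tokens <- strsplit(lines, "\t", fixed = TRUE)
  names <- vapply(tokens, `[[`, character(1), 1L)
  sets <- lapply(tokens, function(tk) tk[-(1:2)])
  ids <- sub("__(top|bottom)$", "", names)
  part <- sub("^.*__", "", names)
  out <- list()
  for (id in unique(ids)) {
    top <- sets[[which(ids == id & part == "top")[1L]]]
    bottom <- sets[[which(ids == id & part == "bottom")[1L]]]
    out[[id]] <- extreme_signature_sets(top, bottom, id = id)
  }
  out
}

#' Write a herb-disease score table as TSV
#' @param scores Data frame from [score_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
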