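# Readers and writers for the package's TSV dialects, plus the containers
# they populate: the phosphorylation profile matrix, the kinase-substrate
# annotation, and the static kinase-site score table.

#' Construct a phosphorylation profile matrix
#'
#' A phospho profile matrix holds fold-change phosphorylation levels of
#' `n` phosphosites (rows, named by canonical site identifiers) across `m`
#' biological states (columns). The row of a site is its *phosphorylation
#' profile*. The constructor validates identifiers, rejects duplicates and
#' missing values, and warns when fewer than 5 states are available (small
#' state counts make correlation estimates noisy).
#'
#' @param values numeric matrix, rownames = canonical site identifiers,
#'   colnames = state labels.
#' @return An object of class `phospho_matrix` (a numeric matrix).
#' @export
phospho_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry site rownames and state colnames")
  }
  if (ncol(values) < 3L) {
    stop("at least 3 biological states are required, got ", ncol(values))
  }
  if (anyNA(values)) {
    stop("missing values are not allowed; filter rows before construction")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate site rows must be aggregated before construction")
  }
  parse_site_id(rownames(values))  # validates identifiers
  if (ncol(values) < 5L) {
    warning("only ", ncol(values),
            " biological states; at least 5 are recommended", call. = FALSE)
  }
  class(values) <- c("phospho_matrix", class(values))
  values
}

#' Read a phosphosite intensity/fold-change matrix
#'
#' Reads a TSV whose header row names the biological states, whose first
#' column (`site`) holds canonical site identifiers, and whose cells are
#' fold-change values. Rows containing any empty or non-numeric cell are
#' dropped; duplicate site rows are aggregated by element-wise mean; both
#' counts are reported via `message()` and stored as attributes
#' `n_dropped` / `n_aggregated`.
#'
#' @param path path to the TSV file.
#' @param log_transform if `TRUE`, replace values by `log2(value)`; requires
#'   all retained values to be strictly positive.
#' @return A [phospho_matrix()].
#' @export
read_intensity_matrix <- function(path, log_transform = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || tolower(names(raw)[1L]) != "site") {
    stop("malformed header: first column must be 'site', found '",
         names(raw)[1L], "'")
  }
  if (ncol(raw) - 1L < 3L) {
    stop("fewer than 3 state columns in ", path)
  }
  sites <- raw[[1L]]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, names(raw)[-1L]))
  empty <- raw[-1L] == "" | is.na(raw[-1L])
  bad_row <- rowSums(is.na(vals) | as.matrix(empty)) > 0L
  if (any(bad_row)) {
    message("dropped ", sum(bad_row),
            " row(s) with missing or non-numeric cells (e.g. ",
            sites[which(bad_row)[1L]], ")")
  }
  vals <- vals[!bad_row, , drop = FALSE]
  sites <- sites[!bad_row]
  n_aggregated <- 0L
  if (anyDuplicated(sites)) {
    n_aggregated <- sum(duplicated(sites))
    message("aggregated ", n_aggregated,
            " duplicate site row(s) by element-wise mean")
    agg <- rowsum(vals, group = sites, reorder = FALSE)
    cnt <- as.vector(table(factor(sites, levels = rownames(agg))))
    vals <- agg / cnt
    sites <- rownames(agg)
  }
  if (log_transform) {
    if (any(vals <= 0)) {
      off <- which(rowSums(vals <= 0) > 0L)[1L]
      stop("log transform requires positive values; offending row: ",
           sites[off])
    }
    vals <- log2(vals)
  }
  rownames(vals) <- sites
  out <- phospho_matrix(vals)
  attr(out, "n_dropped") <- sum(bad_row)
  attr(out, "n_aggregated") <- n_aggregated
  out
}

#' Construct a kinase-substrate annotation
#'
#' An annotation is a set of (kinase, site) associations: the prior knowledge
#' `T` about which kinase phosphorylates which site, with `T_k` the substrate
#' set of kinase `k`. Duplicate associations collapse to one. Kinases with
#' fewer than `min_substrates` annotated sites are removed (predictions based
#' on a single known substrate are unreliable, so the default keeps only
#' kinases with at least two reported substrates).
#'
#' @param kinase character vector of kinase names.
#' @param site_id character vector of canonical site identifiers.
#' @param min_substrates minimum number of annotated substrates a kinase must
#'   retain; kinases below the threshold are dropped.
#' @return Object of class `ksa_annotation`: a data.frame with columns
#'   `kinase` and `site_id`, one row per retained association.
#' @export
ksa_annotation <- function(kinase, site_id, min_substrates = 2L) {
  stopifnot(length(kinase) == length(site_id))
  df <- unique(data.frame(kinase = as.character(kinase),
                          site_id = as.character(site_id),
                          stringsAsFactors = FALSE))
  if (nrow(df) > 0L) {
    parse_site_id(df$site_id)
    keep <- table(df$kinase) >= min_substrates
    dropped <- sum(!keep)
    if (dropped > 0L) {
      message("removed ", dropped, " kinase(s) with fewer than ",
              min_substrates, " substrates")
    }
    df <- df[df$kinase %in% names(keep)[keep], , drop = FALSE]
  } else {
    warning("empty kinase-substrate annotation", call. = FALSE)
  }
  df <- df[order(df$kinase, df$site_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ksa_annotation", "data.frame")
  df
}

#' @export
print.ksa_annotation <- function(x, ...) {
  cat("Kinase-substrate annotation: ", nrow(x), " associations, ",
      length(unique(x$kinase)), " kinases, ",
      length(unique(x$site_id)), " sites\n", sep = "")
  invisible(x)
}

#' All annotated sites (the set T), or the substrates of one kinase (T_k)
#'
#' @param ksa a [ksa_annotation()].
#' @param kinase optional kinase name; if supplied, only that kinase's
#'   substrate sites are returned.
#' @return Character vector of unique site identifiers.
#' @export
ksa_sites <- function(ksa, kinase = NULL) {
  if (!is.null(kinase)) {
    return(unique(ksa$site_id[ksa$kinase == kinase]))
  }
  unique(ksa$site_id)
}

#' @rdname ksa_sites
#' @export
ksa_kinases <- function(ksa) unique(ksa$kinase)

#' Read a kinase-substrate annotation table
#'
#' Reads a TSV with header `kinase`, `substrate`, `site`, where `site` is a
#' residue-position token such as `"S330"`. The substrate protein and the
#' site token are joined into the canonical site identifier.
#'
#' @inheritParams ksa_annotation
#' @param path path to the TSV file.
#' @return A [ksa_annotation()].
#' @export
read_ksa_table <- function(path, min_substrates = 2L) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("kinase", "substrate", "site")
  if (!identical(names(raw)[seq_along(need)], need)) {
    stop("malformed header: expected columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(ksa_annotation(character(), character(),
                          min_substrates = min_substrates))
  }
  tok_ok <- grepl("^[STY][0-9]+$", raw$site)
  if (!all(tok_ok)) {
    stop("unparseable site token '", raw$site[which(!tok_ok)[1L]],
         "' at line ", which(!tok_ok)[1L] + 1L)
  }
  ksa_annotation(raw$kinase, paste0(raw$substrate, "_", raw$site),
                 min_substrates = min_substrates)
}

#' Read a static kinase-site score table
#'
#' Reads pre-computed kinase-site likelihood scores in the style of a
#' KinomeXplorer-DB export: TSV with header `kinase`, `site_id`, `score`.
#' Scores must be strictly positive (they enter the integrated score through
#' `log2`); non-positive entries are skipped with a warning. Conflicting
#' duplicate entries (same kinase and site, different score) are an error.
#'
#' @param path path to the TSV file.
#' @return Object of class `static_scores`: data.frame with columns
#'   `kinase`, `site_id`, `score`.
#' @export
read_static_scores <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("kinase", "site_id", "score")
  if (!identical(names(raw)[seq_along(need)], need)) {
    stop("malformed header: expected columns ",
         paste(need, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(raw$score))
  if (anyNA(score)) {
    stop("non-numeric score at line ", which(is.na(score))[1L] + 1L)
  }
  static_scores(raw$kinase, raw$site_id, score)
}

#' @rdname read_static_scores
#' @param kinase,site_id,score vectors forming the table directly.
#' @export
static_scores <- function(kinase, site_id, score) {
  df <- data.frame(kinase = as.character(kinase),
                   site_id = as.character(site_id),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  nonpos <- df$score <= 0
  if (any(nonpos)) {
    warning("skipped ", sum(nonpos),
            " entr(ies) with non-positive score (log2 domain)",
            call. = FALSE)
    df <- df[!nonpos, , drop = FALSE]
  }
  df <- unique(df)
  key <- paste(df$kinase, df$site_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("conflicting duplicate score for ",
         df$kinase[duplicated(key)][1L], " / ",
         df$site_id[duplicated(key)][1L])
  }
  if (nrow(df) > 0L) parse_site_id(df$site_id)
  df <- df[order(df$kinase, df$site_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("static_scores", "data.frame")
  df
}

# Deterministic numeric formatting that round-trips doubles bit-exactly.
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write and read ranked prediction tables
#'
#' Predictions are written as a TSV with header
#' `site_id`, `rank`, `kinase`, `score`, sorted by (site identifier, rank).
#' Scores are printed with 17 significant digits so that a write/read
#' round-trip reproduces the table bit-exactly.
#'
#' @param table a prediction table (data.frame with the four columns above).
#' @param path output path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns the table.
#' @export
write_predictions <- function(table, path) {
  stopifnot(all(c("site_id", "rank", "kinase", "score") %in% names(table)))
  df <- as.data.frame(table)[, c("site_id", "rank", "kinase", "score")]
  df <- df[order(df$site_id, df$rank), , drop = FALSE]
  lines <- c("site_id\trank\tkinase\tscore",
             if (nrow(df) > 0L)
               paste(df$site_id, df$rank, df$kinase, .fmt_num(df$score),
                     sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer",
                                         "character", "numeric"))
  class(df) <- c("prediction_table", "data.frame")
  df
}
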