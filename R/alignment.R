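# Core containers: validated operon-family alignments, heterologous-site
# indexing, pairwise percent identity.

ALN_ALPHABET <- c("A", "C", "G", "T", "-")

#' Construct an operon-family alignment
#'
#' An `operon_alignment` holds the gapped sequences of all copies of a
#' multicopy gene family (e.g. the seven *E. coli* rRNA operons) for one
#' region. Coordinates are 1-based alignment columns throughout the package.
#'
#' @param rows Character vector of gapped sequences (one per operon copy), or a
#'   character matrix with one row per copy and one column per alignment
#'   column. Lowercase is accepted and uppercased; `U` is mapped to `T`.
#' @param region_id Region label, e.g. `"16S"`, `"23S"`, `"spacer"`.
#' @param operon_ids Copy labels, same length as `rows`; must be unique.
#' @param type Region type: `"gene"` or `"spacer"`. In the spacer the two
#'   length variants swap as whole units, so length polymorphism is allelic.
#' @param allow_N Permit `N` characters. `N` columns are excluded from
#'   heterologous-site indexing.
#' @return An object of class `operon_alignment`: a list with `region_id`,
#'   `operon_ids`, `type`, `n_columns`, and `mat` (character matrix,
#'   copies x columns, rownames = `operon_ids`).
#' @seealso [read_operon_alignment()], [heterologous_sites()],
#'   [mean_pairwise_identity()]
#' @export
operon_alignment <- function(rows, region_id, operon_ids = NULL,
                             type = c("gene", "spacer"), allow_N = FALSE) {
  type <- match.arg(type)
  if (is.matrix(rows)) {
    mat <- rows
    if (is.null(operon_ids)) operon_ids <- rownames(mat)
  } else {
    if (is.null(operon_ids)) operon_ids <- names(rows)
    if (length(rows) < 2L) stop("alignment must have >= 2 rows", call. = FALSE)
    widths <- nchar(rows)
    if (length(unique(widths)) != 1L) {
      stop("alignment-shape error: rows have unequal lengths (",
           paste(widths, collapse = ", "), ")", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  }
  if (is.null(operon_ids)) stop("operon_ids are required", call. = FALSE)
  operon_ids <- as.character(operon_ids)
  if (nrow(mat) < 2L) stop("alignment must have >= 2 rows", call. = FALSE)
  if (ncol(mat) < 1L) stop("alignment must have >= 1 column", call. = FALSE)
  if (length(operon_ids) != nrow(mat)) {
    stop("identity error: ", length(operon_ids), " operon ids for ",
         nrow(mat), " rows", call. = FALSE)
  }
  if (anyDuplicated(operon_ids)) {
    stop("identity error: duplicate operon ids: ",
         paste(unique(operon_ids[duplicated(operon_ids)]), collapse = ", "),
         call. = FALSE)
  }
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  mat[mat == "."] <- "-"
  ok <- ALN_ALPHABET
  if (allow_N) ok <- c(ok, "N")
  bad <- setdiff(unique(as.vector(mat)), ok)
  if (length(bad)) {
    stop("alphabet error: illegal character(s) ",
         paste(sQuote(bad), collapse = ", "), " in alignment ", region_id,
         call. = FALSE)
  }
  dimnames(mat) <- list(operon_ids, NULL)
  structure(
    list(region_id = region_id, operon_ids = operon_ids, type = type,
         n_columns = ncol(mat), mat = mat),
    class = "operon_alignment"
  )
}

#' @export
print.operon_alignment <- function(x, ...) {
  cat("operon_alignment '", x$region_id, "' (", x$type, "): ",
      length(x$operon_ids), " copies x ", x$n_columns, " columns\n", sep = "")
  invisible(x)
}

#' Read a region alignment from an aligned multi-FASTA file
#'
#' Records are matched to `expected_operons` by FASTA id (the first
#' whitespace-delimited token of the header); rows are returned in the order
#' of `expected_operons` regardless of file order.
#'
#' @param path Path to an aligned multi-FASTA file (equal gapped widths).
#' @param region_id Region label.
#' @param expected_operons Character vector of operon labels; each must match
#'   exactly one record id.
#' @inheritParams operon_alignment
#' @return An [operon_alignment()].
#' @export
read_operon_alignment <- function(path, region_id, expected_operons,
                                  type = c("gene", "spacer"),
                                  allow_N = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  hits <- match(expected_operons, ids)
  if (anyNA(hits)) {
    stop("identity error: operon id(s) missing from ", path, ": ",
         paste(expected_operons[is.na(hits)], collapse = ", "), call. = FALSE)
  }
  dup <- expected_operons[expected_operons %in% ids[duplicated(ids)]]
  if (length(dup)) {
    stop("identity error: duplicate record id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  rows <- seqs[hits]
  names(rows) <- expected_operons
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment-shape error: records in ", path,
         " have unequal widths (", paste(widths, collapse = ", "), ")",
         call. = FALSE)
  }
  operon_alignment(rows, region_id = region_id,
                   operon_ids = expected_operons, type = type,
                   allow_N = allow_N)
}

#' Write an operon alignment to FASTA
#'
#' @param aln An [operon_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_operon_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  writeLines(paste0(">", aln$operon_ids, "\n", seqs), path)
  invisible(path)
}

#' Index heterologous sites of a family alignment
#'
#' A heterologous site is an alignment column where at least two copies carry
#' distinct states; only there is a gene conversion detectable. Gaps are
#' treated as a fifth character state, so small indels segregating between
#' copies are indexed like substitutions. Columns containing `N` are excluded.
#'
#' @param aln An [operon_alignment()].
#' @return An object of class `het_sites`: list with `positions` (sorted
#'   1-based columns) and `alleles_at` (character matrix, copies x positions,
#'   column names = positions).
#' @export
heterologous_sites <- function(aln) {
  stopifnot(inherits(aln, "operon_alignment"))
  m <- aln$mat
  has_n <- colSums(m == "N") > 0L
  # a column is heterologous iff not all rows equal its first row
  diff_first <- colSums(m != m[rep(1L, nrow(m)), , drop = FALSE]) > 0L
  pos <- which(diff_first & !has_n)
  alleles <- m[, pos, drop = FALSE]
  colnames(alleles) <- pos
  structure(list(region_id = aln$region_id, positions = as.integer(pos),
                 alleles_at = alleles),
            class = "het_sites")
}

#' @export
print.het_sites <- function(x, ...) {
  cat("het_sites '", x$region_id, "': ", length(x$positions),
      " heterologous column(s)\n", sep = "")
  invisible(x)
}

#' Pairwise percent identity of a family alignment
#'
#' Identity for a pair of rows is the number of columns at which the two rows
#' carry the identical character (two aligned gaps match; gap vs. base
#' mismatches) divided by the total alignment length, times 100. The mean is
#' the arithmetic mean over the n(n-1)/2 unordered pairs.
#'
#' @param aln An [operon_alignment()], or a list of alignments sharing the
#'   same copies, which are concatenated column-wise before the computation.
#' @return An object of class `identity_matrix`: list with `matrix` (percent,
#'   symmetric, diagonal 100) and `mean` (percent).
#' @export
mean_pairwise_identity <- function(aln) {
  if (inherits(aln, "operon_alignment")) aln <- list(aln)
  stopifnot(length(aln) >= 1L, all(vapply(aln, inherits, TRUE, "operon_alignment")))
  ids <- aln[[1L]]$operon_ids
  for (a in aln) {
    if (!identical(a$operon_ids, ids)) {
      stop("alignments to concatenate must share operon ids in order",
           call. = FALSE)
    }
  }
  m <- do.call(cbind, lapply(aln, `[[`, "mat"))
  n <- nrow(m)
  L <- ncol(m)
  if (L == 0L) stop("empty alignment", call. = FALSE)
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      idm[i, j] <- idm[j, i] <- 100 * sum(m[i, ] == m[j, ]) / L
    }
  }
  structure(list(matrix = idm, mean = mean(idm[upper.tri(idm)])),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("identity_matrix: mean pairwise identity ",
      formatC(x$mean, digits = 3, format = "f"), "%\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Read a region map configuration
#'
#' A region map is a YAML file listing, for each region, the alignment file
#' path, the operon labels, and the region type (`gene` or `spacer`):
#' ```yaml
#' operons: [rrnA, rrnB, rrnC, rrnD, rrnE, rrnG, rrnH]
#' regions:
#'   - region_id: 16S
#'     path: ancestor_16S.fasta
#'     type: gene
#' ```
#' Relative paths are resolved against the directory containing the map.
#'
#' @param path Path to the YAML region map.
#' @return List with `operons` and `regions` (each a list with `region_id`,
#'   `path` (absolute), `type`).
#' @export
read_region_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$operons) || is.null(cfg$regions)) {
    stop("region map must define 'operons' and 'regions'", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  cfg$regions <- lapply(cfg$regions, function(r) {
    if (is.null(r$region_id) || is.null(r$path)) {
      stop("each region needs 'region_id' and 'path'", call. = FALSE)
    }
    if (is.null(r$type)) r$type <- "gene"
    if (!r$type %in% c("gene", "spacer")) {
      stop("region type must be 'gene' or 'spacer'", call. = FALSE)
    }
    if (!grepl("^(/|[A-Za-z]:)", r$path)) r$path <- file.path(base, r$path)
    r
  })
  cfg
}

#' Load all alignments named by a region map
#'
#' @param map A region map from [read_region_map()].
#' @param suffix Optional suffix inserted before the file extension, used to
#'   pick per-lineage files that sit next to the ancestral ones.
#' @return Named list of [operon_alignment()]s, one per region.
#' @export
load_region_alignments <- function(map, suffix = NULL) {
  alns <- lapply(map$regions, function(r) {
    p <- r$path
    if (!is.null(suffix)) {
      p <- sub("(\\.[A-Za-z0-9]+)$", paste0(suffix, "\\1"), p)
    }
    read_operon_alignment(p, region_id = r$region_id,
                          expected_operons = map$operons, type = r$type)
  })
  names(alns) <- vapply(map$regions, `[[`, "", "region_id")
  alns
}
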