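#' Assemble and validate a genotype matrix
#'
#' Bundles per-individual metadata, a marker panel and a rectangular table of
#' codominant genotype calls into the container used by every scan in the
#' package. Calls are stored as character tokens `"AA"` (homozygous for the
#' P1 parental line), `"AB"` (heterozygous), `"BB"` (homozygous P2), with
#' `NA` for failed calls.
#'
#' @param individuals Data frame with columns `id`, `cohort` (one of
#'   `"f2_nauplii"`, `"f2_adult_male"`, `"nrbc_adult_male"`), `family` (F1
#'   pair label) and `sex` (`"male"`, `"female"` or `"unknown"`); an optional
#'   `mito` column (`"P1"`/`"P2"`) defaults to `"P1"`, the cytoplasmic
#'   background every F2 and backcross individual inherits from the maternal
#'   line.
#' @param markers Data frame with column `name` and optional columns
#'   `chromosome`, `position_cM` (non-negative) and `marker_class`
#'   (`"snp"` or `"microsatellite"`).
#' @param calls Character matrix of calls, one row per individual and one
#'   column per marker.
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `individuals`, `markers` and `calls`.
#' @export
#' @examples
#' ind <- data.frame(id = c("i1", "i2"), cohort = "f2_nauplii",
#'                   family = "F1P01", sex = "unknown")
#' mk <- data.frame(name = c("m1", "m2"))
#' gm <- genotype_matrix(ind, mk, matrix(c("AA", "AB", "BB", NA), 2, 2))
#' genotype_counts(gm, "m1", "f2_nauplii")
genotype_matrix <- function(individuals, markers, calls) {
  individuals <- as.data.frame(individuals)
  markers <- as.data.frame(markers)
  if (is.null(individuals$mito)) {
    individuals$mito <- rep("P1", nrow(individuals))
  }
  for (col in c("chromosome", "marker_class")) {
    if (is.null(markers[[col]])) {
      markers[[col]] <- rep(NA_character_, nrow(markers))
    }
  }
  if (is.null(markers$position_cM)) {
    markers$position_cM <- rep(NA_real_, nrow(markers))
  }
  calls <- as.matrix(calls)
  mode(calls) <- "character"
  rownames(calls) <- individuals$id
  colnames(calls) <- markers$name
  gm <- structure(list(individuals = individuals, markers = markers,
                       calls = calls),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype matrix
#'
#' Checks the structural invariants of a [genotype_matrix()]: rectangular
#' call table matching the metadata, unique identifiers, legal enum values,
#' legal genotype tokens and non-negative map positions. A `HOM_P1` (`"AA"`)
#' call inside a non-recombinant backcross cohort is impossible under the
#' cross design (every NR-BC individual carries a whole-P2 paternal
#' chromosome) and raises a warning naming the offending cells, since such
#' calls can only arise as genotyping artifacts.
#'
#' @param gm A `"genotype_matrix"` object.
#' @return `gm`, invisibly; called for its side effect of stopping on
#'   malformed input.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ind <- gm$individuals
  mk <- gm$markers
  for (col in c("id", "cohort", "family", "sex", "mito")) {
    if (is.null(ind[[col]])) stop("individuals table lacks column '", col, "'")
  }
  if (anyDuplicated(ind$id)) stop("individual ids are not unique")
  bad <- setdiff(unique(ind$cohort), .cohorts)
  if (length(bad)) stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ind$sex), .sexes)
  if (length(bad)) stop("unknown sex label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ind$mito), c("P1", "P2"))
  if (length(bad)) stop("unknown mito label(s): ", paste(bad, collapse = ", "))
  if (is.null(mk$name)) stop("marker table lacks column 'name'")
  if (anyDuplicated(mk$name)) stop("marker names are not unique")
  if (any(!is.na(mk$position_cM) & mk$position_cM < 0)) {
    stop("negative position_cM in marker table")
  }
  bad <- setdiff(unique(mk$marker_class[!is.na(mk$marker_class)]),
                 c("snp", "microsatellite"))
  if (length(bad)) stop("unknown marker_class: ", paste(bad, collapse = ", "))
  calls <- gm$calls
  if (nrow(calls) != nrow(ind) || ncol(calls) != nrow(mk)) {
    stop("call table is ", nrow(calls), " x ", ncol(calls),
         " but metadata describe ", nrow(ind), " individuals and ",
         nrow(mk), " markers")
  }
  ok <- is.na(calls) | calls %in% .geno_tokens
  if (!all(ok)) {
    w <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid genotype token '", calls[w[1], w[2]], "' for individual '",
         ind$id[w[1]], "', marker '", mk$name[w[2]], "'")
  }
  nrbc <- ind$cohort == "nrbc_adult_male"
  if (any(nrbc)) {
    aa <- which(calls[nrbc, , drop = FALSE] == "AA", arr.ind = TRUE)
    if (nrow(aa)) {
      ids <- ind$id[nrbc][aa[, 1]]
      warning(nrow(aa), " HOM_P1 (AA) call(s) in NR-BC cohort, impossible ",
              "under the cross design; likely genotyping artifacts (e.g. ",
              ids[1], " at ", mk$name[aa[1, 2]], ")")
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$individuals$cohort)
  cat("genotype_matrix: ", nrow(x$calls), " individuals x ",
      ncol(x$calls), " markers\n", sep = "")
  cat("  cohorts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Read a genotype table from CSV
#'
#' Expects a header row `individual_id, cohort, family, sex[, mito]` followed
#' by one column per marker; cells must be `AA`, `AB`, `BB` or `NA`.
#'
#' @param path Path to a CSV file.
#' @return A validated [genotype_matrix()].
#' @export
read_genotype_table <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 na.strings = character(0))
  need <- c("individual_id", "cohort", "family", "sex")
  for (col in need) {
    if (!col %in% names(df)) {
      stop("genotype table '", path, "' lacks mandatory column '", col, "'")
    }
  }
  meta_cols <- c(need, if ("mito" %in% names(df)) "mito")
  marker_cols <- setdiff(names(df), meta_cols)
  if (!length(marker_cols)) stop("genotype table '", path, "' has no marker columns")
  calls <- as.matrix(df[marker_cols])
  calls[calls == "NA" | calls == ""] <- NA_character_
  ok <- is.na(calls) | calls %in% .geno_tokens
  if (!all(ok)) {
    w <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid genotype token '", calls[w[1], w[2]], "' at row ", w[1],
         ", marker '", marker_cols[w[2]], "' in '", path, "'")
  }
  ind <- data.frame(id = df$individual_id, cohort = df$cohort,
                    family = df$family, sex = df$sex,
                    mito = if ("mito" %in% names(df)) df$mito else "P1")
  genotype_matrix(ind, data.frame(name = marker_cols), calls)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]: metadata columns first, then one
#' column per marker in panel order, `MISSING` serialized as `NA`.
#'
#' @param gm A `"genotype_matrix"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path) {
  validate_genotype_matrix(gm)
  ind <- gm$individuals
  df <- data.frame(individual_id = ind$id, cohort = ind$cohort,
                   family = ind$family, sex = ind$sex, mito = ind$mito,
                   check.names = FALSE)
  calls <- gm$calls
  calls[is.na(calls)] <- "NA"
  df <- cbind(df, as.data.frame(calls, optional = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a marker map table
#'
#' The marker map is a TSV with header `marker, chromosome, position_cM,
#' marker_class`; the same schema carries the simulator's genome layout and
#' the mapping output, so simulation truth and inference are directly
#' comparable.
#'
#' @param path Path to a TSV file.
#' @return For `read_marker_map`, a data frame with columns `name`,
#'   `chromosome`, `position_cM`, `marker_class`.
#' @export
read_marker_map <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE,
                 colClasses = c("character", "character", "numeric",
                                "character"))
  need <- c("marker", "chromosome", "position_cM", "marker_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("marker map '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- data.frame(name = df$marker, chromosome = df$chromosome,
                    position_cM = df$position_cM,
                    marker_class = df$marker_class)
  if (anyDuplicated(out$name)) stop("duplicate marker names in '", path, "'")
  out
}

#' @param markers Marker data frame as returned by [read_marker_map()] or
#'   stored in a genotype matrix.
#' @rdname read_marker_map
#' @export
write_marker_map <- function(markers, path) {
  df <- data.frame(marker = markers$name, chromosome = markers$chromosome,
                   position_cM = markers$position_cM,
                   marker_class = markers$marker_class)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach map information to a genotype matrix
#'
#' Merges chromosome, position and class columns from a marker map into the
#' marker table of a genotype matrix (matched by name).
#'
#' @inheritParams write_genotype_table
#' @param map Marker map data frame (see [read_marker_map()]).
#' @return The genotype matrix with enriched marker metadata.
#' @export
attach_marker_map <- function(gm, map) {
  i <- match(gm$markers$name, map$name)
  if (anyNA(i)) {
    stop("marker(s) absent from map: ",
         paste(gm$markers$name[is.na(i)], collapse = ", "))
  }
  gm$markers$chromosome <- map$chromosome[i]
  gm$markers$position_cM <- map$position_cM[i]
  gm$markers$marker_class <- map$marker_class[i]
  gm
}

#' Genotype counts for one marker within one cohort
#'
#' @inheritParams write_genotype_table
#' @param marker Marker name.
#' @param cohort Cohort label.
#' @return Named integer vector `n_het`, `n_hom_p1`, `n_hom_p2`,
#'   `n_missing`; the four counts always sum to the cohort size.
#' @export
genotype_counts <- function(gm, marker, cohort) {
  j <- match(marker, gm$markers$name)
  if (is.na(j)) stop("unknown marker '", marker, "'")
  rows <- gm$individuals$cohort == cohort
  if (!any(rows)) stop("no individuals in cohort '", cohort, "'")
  v <- gm$calls[rows, j]
  c(n_het = sum(v == "AB", na.rm = TRUE),
    n_hom_p1 = sum(v == "AA", na.rm = TRUE),
    n_hom_p2 = sum(v == "BB", na.rm = TRUE),
    n_missing = sum(is.na(v)))
}

# Integer-coded calls (1 = HOM_P1, 2 = HET, 3 = HOM_P2, NA = missing) for
# one cohort; used by the scan machinery.
.cohort_geno <- function(gm, cohort) {
  rows <- gm$individuals$cohort == cohort
  if (!any(rows)) stop("no individuals in cohort '", cohort, "'")
  g <- gm$calls[rows, , drop = FALSE]
  out <- matrix(match(g, .geno_tokens), nrow(g), ncol(g))
  colnames(out) <- gm$markers$name
  out
}
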