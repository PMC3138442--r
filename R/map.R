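#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure of the significance relation: two
#' markers fall in the same group when any chain of marker pairs with
#' `p_linkage < alpha` (and, optionally, `r_hat <= max_r`) connects them.
#' Markers with no significant partner become singleton groups.
#'
#' @param pairwise Data frame from [two_point_scan()] (columns `marker_a`,
#'   `marker_b`, `p_linkage`, `r_hat`).
#' @param markers Character vector of all marker names to partition.
#' @param alpha Linkage criterion on the two-point likelihood-ratio p-value
#'   (default 0.001).
#' @param max_r Additional ceiling on the estimated recombination fraction
#'   for a pair to count as linked. The default `0.5` disables it,
#'   implementing the pure p-value closure; [build_map()] tightens it to
#'   guard a genome-wide scan against single false-positive joins.
#' @return Named character vector mapping each marker to a group label
#'   (`"LG01"`, `"LG02"`, ... in order of first marker appearance).
#' @export
group_markers <- function(pairwise, markers, alpha = 0.001, max_r = 0.5) {
  n <- length(markers)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sig <- pairwise$p_linkage < alpha & pairwise$r_hat <= max_r
  ia <- match(pairwise$marker_a, markers)
  ib <- match(pairwise$marker_b, markers)
  for (k in which(sig)) {
    ra <- find(ia[k])
    rb <- find(ib[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  labels <- sprintf("LG%02d", match(root, unique(root)))
  names(labels) <- markers
  labels
}

# All permutations of v (m <= 8 in practice).
.permutations <- function(v) {
  n <- length(v)
  if (n <= 1L) return(matrix(v, nrow = 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- .permutations(v[-i])
    out[[i]] <- cbind(v[i], rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

.sarf <- function(ord, rmat) {
  m <- length(ord)
  sum(rmat[cbind(ord[-m], ord[-1L])])
}

#' Order the markers of a linkage group
#'
#' Finds the marker order minimizing the sum of adjacent recombination
#' fractions (SARF): exhaustive search over permutations for groups of up
#' to 8 markers, greedy end-insertion followed by 2-opt refinement for
#' larger groups. The orientation is canonicalized so the first marker name
#' sorts before the last.
#'
#' @param members Character vector of marker names (length >= 2).
#' @param rmat Symmetric numeric matrix of pairwise `r_hat`, with marker
#'   names on both dimnames.
#' @return Character vector: the ordered markers.
#' @export
order_group <- function(members, rmat) {
  m <- length(members)
  if (m < 2L) stop("a group must contain at least two markers to order")
  r <- rmat[members, members, drop = FALSE]
  idx <- seq_len(m)
  if (m == 2L) {
    ord <- idx
  } else if (m <= 8L) {
    perms <- .permutations(idx)
    scores <- apply(perms, 1L, .sarf, rmat = r)
    ord <- perms[which.min(scores), ]
  } else {
    # greedy: start from the tightest pair, extend at whichever end is
    # closer to an unplaced marker
    start <- which(r == min(r[upper.tri(r)]), arr.ind = TRUE)[1L, ]
    ord <- as.integer(start)
    left <- setdiff(idx, ord)
    while (length(left)) {
      d_head <- r[ord[1L], left]
      d_tail <- r[ord[length(ord)], left]
      if (min(d_head) < min(d_tail)) {
        ord <- c(left[which.min(d_head)], ord)
      } else {
        ord <- c(ord, left[which.min(d_tail)])
      }
      left <- setdiff(idx, ord)
    }
    # 2-opt: reverse internal segments while that lowers SARF
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(m - 1L)) {
        for (j in seq(i + 1L, m)) {
          cand <- ord
          cand[i:j] <- rev(cand[i:j])
          if (.sarf(cand, r) < .sarf(ord, r) - 1e-12) {
            ord <- cand
            improved <- TRUE
          }
        }
      }
    }
  }
  out <- members[ord]
  if (out[1L] > out[length(out)]) out <- rev(out)
  out
}

#' Build linkage group maps from a genotype matrix
#'
#' The full two-point mapping pipeline: pairwise recombination estimates
#' ([two_point_scan()]), linkage grouping at `alpha` ([group_markers()]),
#' SARF ordering within groups ([order_group()]), and cumulative Kosambi
#' positions from adjacent `r_hat`. Adjacent fractions at the `r = 0.5`
#' boundary are clamped just below it before the Kosambi transform.
#'
#' Unlike the pure closure in [group_markers()], grouping here additionally
#' requires `r_hat <= group_max_r` (default 0.35) for a pair to join two
#' groups — the standard two-point mapping safeguard against one spurious
#' p-value chaining two chromosomes together in a genome-wide scan.
#'
#' @inheritParams two_point_scan
#' @param alpha Linkage criterion (p-value threshold, default 0.001).
#' @param group_max_r Recombination-fraction ceiling used during grouping.
#' @return Object of class `"linkage_map"`: list with `groups` (data frame
#'   `group`, `marker`, `position_cM`), `lengths` (data frame `group`, `m`,
#'   `length_cM`), `assignment` (marker -> group vector), `pairwise` (the
#'   two-point scan) and the options used.
#' @export
build_map <- function(gm, cohort,
                      sex_model = c("symmetric", "female_achiasmatic"),
                      alpha = 0.001, group_max_r = 0.35) {
  sex_model <- match.arg(sex_model)
  tp <- two_point_scan(gm, cohort, sex_model)
  markers <- gm$markers$name
  assignment <- group_markers(tp, markers, alpha = alpha, max_r = group_max_r)
  rmat <- matrix(0.5, length(markers), length(markers),
                 dimnames = list(markers, markers))
  diag(rmat) <- 0
  rmat[cbind(tp$marker_a, tp$marker_b)] <- tp$r_hat
  rmat[cbind(tp$marker_b, tp$marker_a)] <- tp$r_hat
  groups <- list()
  lengths <- list()
  for (gid in unique(assignment)) {
    members <- names(assignment)[assignment == gid]
    if (length(members) == 1L) {
      pos <- 0
      ord <- members
    } else {
      ord <- order_group(members, rmat)
      r_adj <- rmat[cbind(ord[-length(ord)], ord[-1L])]
      r_adj <- pmin(r_adj, 0.5 - 1e-6)
      pos <- c(0, cumsum(kosambi_cm(r_adj)))
    }
    groups[[gid]] <- data.frame(group = gid, marker = ord, position_cM = pos)
    lengths[[gid]] <- data.frame(group = gid, m = length(ord),
                                 length_cM = pos[length(pos)])
  }
  structure(list(groups = do.call(rbind, c(groups, make.row.names = FALSE)),
                 lengths = do.call(rbind, c(lengths, make.row.names = FALSE)),
                 assignment = assignment,
                 pairwise = tp,
                 cohort = cohort, sex_model = sex_model,
                 alpha = alpha, group_max_r = group_max_r),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("linkage_map (", x$cohort, ", ", x$sex_model, " model): ",
      nrow(x$lengths), " groups, ", nrow(x$groups), " markers\n", sep = "")
  print(x$lengths, row.names = FALSE)
  invisible(x)
}

#' Construct a linkage map from known marker positions
#'
#' Builds the same `"linkage_map"` container as [build_map()] directly from
#' per-group cumulative positions — useful for summarizing a published map
#' or the simulator's true layout with [map_summary()].
#'
#' @param positions Named list; each element a numeric vector of
#'   non-decreasing cumulative positions (cM), optionally named by marker.
#' @return A `"linkage_map"` object (without pairwise estimates).
#' @export
map_from_positions <- function(positions) {
  stopifnot(is.list(positions), length(positions) > 0)
  groups <- list()
  lengths <- list()
  for (gid in names(positions)) {
    pos <- positions[[gid]]
    if (is.unsorted(pos)) stop("positions in group '", gid, "' must be non-decreasing")
    mk <- names(pos)
    if (is.null(mk)) mk <- sprintf("%s.%d", gid, seq_along(pos))
    groups[[gid]] <- data.frame(group = gid, marker = mk, position_cM = pos)
    lengths[[gid]] <- data.frame(group = gid, m = length(pos),
                                 length_cM = pos[length(pos)] - pos[1L])
  }
  structure(list(groups = do.call(rbind, c(groups, make.row.names = FALSE)),
                 lengths = do.call(rbind, c(lengths, make.row.names = FALSE)),
                 assignment = NULL, pairwise = NULL,
                 cohort = NA_character_, sex_model = NA_character_,
                 alpha = NA_real_, group_max_r = NA_real_),
            class = "linkage_map")
}

#' Genome coverage of a marker map
#'
#' Expected fraction of the genome within `d` cM of some marker,
#' `c = 1 - exp(-2 d n / L)`, where `d` is the mean intermarker distance,
#' `n` the number of markers assigned to (multi-marker) linkage groups and
#' `L` the corrected total map length.
#'
#' @param d Mean intermarker distance (cM).
#' @param n Number of mapped markers.
#' @param L Corrected map length (cM).
#' @return Coverage as a fraction in `[0, 1]`.
#' @export
#' @examples
#' genome_coverage(6.5, 52, 484.8)  # ~0.752
genome_coverage <- function(d, n, L) {
  stopifnot(d >= 0, n >= 0, L > 0)
  1 - exp(-2 * d * n / L)
}

#' Map length, spacing, corrected length and genome coverage
#'
#' Summarizes a linkage map with the standard corrected-length and coverage
#' estimators: each multi-marker group contributes its observed length plus
#' 2 cM, inflated by `(m + 1) / (m - 1)` where `m` is its marker count;
#' total length, the mean intermarker distance `d = total / sum(m - 1)` and
#' the marker count `n` are taken over multi-marker groups only (the
#' correction factor is undefined for singletons, which are reported but
#' excluded); coverage comes from [genome_coverage()].
#'
#' @param map A `"linkage_map"` from [build_map()] or
#'   [map_from_positions()].
#' @return Object of class `"map_summary"`: list with `total_length`, `d`,
#'   `n_markers`, `corrected_length`, `coverage`, `n_groups`,
#'   `n_singletons`.
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "linkage_map"))
  len <- map$lengths
  multi <- len$m >= 2L
  if (!any(multi)) {
    stop("map length correction is undefined when every group is a singleton")
  }
  total <- sum(len$length_cM[multi])
  d <- total / sum(len$m[multi] - 1L)
  n <- sum(len$m[multi])
  L <- sum((len$length_cM[multi] + 2) * (len$m[multi] + 1) /
             (len$m[multi] - 1))
  structure(list(total_length = total, d = d, n_markers = n,
                 corrected_length = L, coverage = genome_coverage(d, n, L),
                 n_groups = nrow(len), n_singletons = sum(!multi)),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf(paste0("map_summary: %d groups (%d singleton), n = %d mapped",
                     " markers\n  total %.1f cM, mean spacing %.1f cM,",
                     " corrected %.1f cM, coverage %.1f%%\n"),
              x$n_groups, x$n_singletons, x$n_markers, x$total_length,
              x$d, x$corrected_length, 100 * x$coverage))
  invisible(x)
}
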