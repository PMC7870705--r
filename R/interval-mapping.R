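#' Ordered marker map
#'
#' An ordered set of markers along a chromosome region, with optional
#' physical (`bp`) and genetic (`cm`) positions. Positions, when given,
#' must strictly increase along the order.
#'
#' @param marker Character vector of unique marker names, in map order.
#' @param bp Optional integer physical positions.
#' @param cm Optional numeric genetic positions (centimorgans); required
#'   by [simulate_marker_population()].
#' @return A tibble of class `marker_map`.
#' @examples
#' marker_map(c("M48", "M46"), bp = c(1, 18400))
#' @export
marker_map <- function(marker, bp = NULL, cm = NULL) {
  marker <- as.character(marker)
  if (length(marker) < 2L) {
    abort("A marker map needs at least two markers.")
  }
  if (anyDuplicated(marker)) {
    abort("Marker names must be unique.")
  }
  check_incr <- function(x, nm) {
    if (!is.null(x)) {
      if (length(x) != length(marker)) {
        abort(sprintf("`%s` must match the number of markers.", nm))
      }
      if (any(diff(x) <= 0)) {
        abort(sprintf("`%s` positions must strictly increase.", nm))
      }
    }
  }
  check_incr(bp, "bp")
  check_incr(cm, "cm")
  out <- tibble(marker = marker,
                bp = if (is.null(bp)) NA_integer_ else as.integer(bp),
                cm = if (is.null(cm)) NA_real_ else as.numeric(cm))
  class(out) <- c("marker_map", class(out))
  out
}

GENO_CODES <- c("T", "H", "G")

# normalize a vector of genotype calls: "-"/""/NA -> NA, validate codes
normalize_calls <- function(calls, context = "genotype") {
  calls <- as.character(calls)
  calls[calls %in% c("-", "", "NA")] <- NA_character_
  bad <- !is.na(calls) & !calls %in% GENO_CODES
  if (any(bad)) {
    abort(sprintf("Unknown %s code(s): %s (expected T, H, G or missing).",
                  context, paste(unique(calls[bad]), collapse = ", ")))
  }
  calls
}

record_calls <- function(record, map) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) {
      abort("`record` must be a single plant (one row).")
    }
    missing_m <- setdiff(map$marker, names(record))
    if (length(missing_m) > 0) {
      abort(sprintf("Record lacks marker column(s): %s.",
                    paste(missing_m, collapse = ", ")))
    }
    calls <- unlist(record[map$marker], use.names = FALSE)
  } else {
    calls <- record
    if (!is.null(names(calls))) {
      calls <- calls[map$marker]
    }
    if (length(calls) != nrow(map)) {
      abort("`record` must supply one call per map marker.")
    }
  }
  normalize_calls(calls)
}

#' Locate recombination breakpoints in one plant
#'
#' Finds the intervals between adjacent markers where a plant's genotype
#' call changes -- each change between consecutive non-missing calls marks
#' one crossover interval. Missing calls widen the interval across them.
#'
#' @param record A named character vector of genotype calls (`T`, `H`,
#'   `G`, or missing as `NA`/`"-"`) in map order, or a one-row data frame
#'   with one column per marker.
#' @param map A [marker_map()].
#' @return A tibble with columns `left`, `right` (flanking marker names),
#'   one row per breakpoint; zero rows when the plant is non-recombinant.
#' @examples
#' m <- marker_map(paste0("m", 1:4))
#' breakpoint_intervals(c("T", "T", "H", "H"), m)
#' @export
breakpoint_intervals <- function(record, map) {
  stopifnot(inherits(map, "marker_map"))
  calls <- record_calls(record, map)
  idx <- which(!is.na(calls))
  if (length(idx) == 0L) {
    abort("All genotype calls are missing; no breakpoints definable.")
  }
  chg <- which(calls[idx[-1]] != calls[idx[-length(idx)]])
  tibble(left = map$marker[idx[chg]], right = map$marker[idx[chg + 1]])
}

PHENOTYPE_SS <- c("SS", "S22A_SS", "S22B_SS", "S22A+B_SS")

implied_call <- function(phenotype) {
  if (phenotype %in% PHENOTYPE_SS) {
    "H"
  } else if (phenotype == "N") {
    "T"
  } else {
    abort(sprintf("Unknown phenotype \"%s\" (expected N or SS).", phenotype))
  }
}

# Allowed-position "slots" along a map of M markers: odd slots 1,3,...
# are markers, even slots are the gaps between adjacent markers
# (2M - 1 slots). The locus model is: a semi-sterile plant is
# heterozygous at the locus, a fertile plant homozygous T; a marker slot
# is allowed when the call there equals the implied call (missing calls
# are compatible -- they widen, never tighten). A gap is allowed when
# the implied locus genotype is achievable between its flanking marker
# genotypes: writing x, y in {0,1,2} wild-allele doses for the flanks,
# each of the plant's two gametes may cross over once inside the gap, so
# the achievable locus doses are exactly max(0, x+y-2) .. min(2, x+y)
# (e.g. flanks T and G can bracket a heterozygous locus: the two gametes
# recombined in opposite directions).
allowed_slots <- function(calls, phenotype) {
  want <- implied_call(phenotype)
  dose <- match(calls, GENO_CODES) - 1L   # T/H/G -> 0/1/2, NA for missing
  c_dose <- match(want, GENO_CODES) - 1L
  mk <- is.na(calls) | calls == want
  M <- length(calls)
  slots <- logical(2 * M - 1)
  slots[seq(1, 2 * M - 1, by = 2)] <- mk
  if (M > 1) {
    x <- dose[-M]
    y <- dose[-1]
    gap_ok <- is.na(x) | is.na(y) |
      (pmax(0L, x + y - 2L) <= c_dose & c_dose <= pmin(2L, x + y))
    slots[seq(2, 2 * M - 2, by = 2)] <- gap_ok
  }
  slots
}

# Convert an allowed-slot vector to flanking-marker intervals. A run
# reaching a map edge is closed at the terminal marker ("[m1" / "mM]");
# an interior boundary is the exclusive flanking marker set by some
# plant's breakpoint ("(m2" / "m5)").
slots_to_intervals <- function(slots, map) {
  M <- nrow(map)
  r <- rle(slots)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  purrr::map_dfr(runs, function(i) {
    s <- starts[i]
    e <- ends[i]
    if (s == 1) {
      left <- map$marker[1]
      left_open <- FALSE
    } else {
      left_idx <- if (s %% 2 == 0) s / 2 else (s - 1) / 2
      left <- map$marker[left_idx]
      left_open <- TRUE
    }
    if (e == 2 * M - 1) {
      right <- map$marker[M]
      right_open <- FALSE
    } else {
      right_idx <- if (e %% 2 == 0) e / 2 + 1 else (e + 1) / 2 + 1
      right <- map$marker[right_idx]
      right_open <- TRUE
    }
    tibble(left = left, right = right,
           left_open = left_open, right_open = right_open)
  })
}

#' Delimit a sterility locus from recombinant plants
#'
#' Localizes a gametophytic sterility locus by intersecting per-plant
#' constraints: under the 1:1:0 selfing model a semi-sterile (SS) plant
#' is heterozygous at the locus and a normally fertile (N) plant is
#' homozygous for the functional allele, so each plant restricts the
#' locus to the maximal marker span where its genotype call matches the
#' call implied by its phenotype. A homozygous-wild (`G`) call is
#' incompatible with either phenotype and so excludes its surroundings;
#' missing calls are compatible with anything (conservative widening).
#' The returned interval is the intersection over all plants, reported as
#' flanking markers (exclusive on a side whenever a plant's breakpoint
#' tightened it). An empty intersection raises a conflicting-recombinants
#' error naming the plants involved, the signature of a phenotyping or
#' genotyping error -- or of a second locus.
#'
#' @param records A data frame with one row per plant: optional
#'   `plant_id`, one column per map marker (codes `T`, `H`, `G`, `-`),
#'   and a `phenotype` column (`N` or `SS`; the sterile-pollen morphology
#'   labels `S22A_SS`, `S22B_SS`, `S22A+B_SS` are accepted and treated
#'   as SS).
#' @param map A [marker_map()].
#' @return An object of class `candidate_interval`: a list with
#'   `intervals` (tibble of flanking markers and open/closed flags,
#'   normally one row), `informative` (ids of plants that set a final
#'   boundary), `n_plants`, `span_bp` (when the map has physical
#'   positions), and the map.
#' @examples
#' m <- marker_map(paste0("m", 1:4))
#' rec <- tibble::tibble(plant_id = "p1", m1 = "T", m2 = "T", m3 = "H",
#'                       m4 = "H", phenotype = "SS")
#' delimit_locus(rec, m)
#' @export
delimit_locus <- function(records, map) {
  stopifnot(inherits(map, "marker_map"))
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    abort("`records` is empty.")
  }
  if (!"phenotype" %in% names(records)) {
    abort("`records` must contain a `phenotype` column.")
  }
  ids <- if ("plant_id" %in% names(records)) {
    as.character(records$plant_id)
  } else {
    as.character(seq_len(nrow(records)))
  }
  M <- nrow(map)
  missing_m <- setdiff(map$marker, names(records))
  if (length(missing_m) > 0) {
    abort(sprintf("Records lack marker column(s): %s.",
                  paste(missing_m, collapse = ", ")))
  }
  call_mat <- t(as.matrix(records[map$marker]))  # markers x plants
  call_mat <- matrix(normalize_calls(call_mat), nrow = M)

  slot_list <- lapply(seq_len(nrow(records)), function(i) {
    allowed_slots(call_mat[, i], records$phenotype[i])
  })
  inter <- Reduce(`&`, slot_list)
  if (!any(inter)) {
    # walk the intersection to name the plant where it first emptied
    acc <- slot_list[[1]]
    culprit <- ids[1]
    for (i in seq_along(slot_list)[-1]) {
      nxt <- acc & slot_list[[i]]
      if (!any(nxt)) {
        culprit <- ids[i]
        break
      }
      acc <- nxt
    }
    abort(sprintf(paste("Conflicting recombinants: constraints from plant",
                        "%s are incompatible with the remaining plants",
                        "(possible phenotyping/genotyping error or a",
                        "second locus)."), culprit))
  }
  intervals <- slots_to_intervals(inter, map)

  # informative plants: those whose individual allowed region sets the
  # final left or right boundary (interior boundaries only)
  fin_first <- which(inter)[1]
  fin_last <- utils::tail(which(inter), 1)
  informative <- character(0)
  for (i in seq_along(slot_list)) {
    s <- slot_list[[i]]
    own_first <- which(s)[1]
    own_last <- utils::tail(which(s), 1)
    if ((fin_first > 1 && own_first == fin_first) ||
        (fin_last < 2 * M - 1 && own_last == fin_last)) {
      informative <- c(informative, ids[i])
    }
  }
  span_bp <- NA_real_
  if (nrow(intervals) == 1L && !anyNA(map$bp)) {
    span_bp <- map$bp[match(intervals$right, map$marker)] -
      map$bp[match(intervals$left, map$marker)]
  }
  if (nrow(intervals) > 1L) {
    warn("Allowed region is non-contiguous; returning all segments.")
  }
  structure(list(intervals = intervals, informative = unique(informative),
                 n_plants = nrow(records), span_bp = span_bp, map = map,
                 slots = inter),
            class = "candidate_interval")
}

#' @export
print.candidate_interval <- function(x, ...) {
  iv <- x$intervals
  for (i in seq_len(nrow(iv))) {
    cat(sprintf("<candidate_interval> %s%s, %s%s\n",
                if (iv$left_open[i]) "(" else "[",
                iv$left[i], iv$right[i],
                if (iv$right_open[i]) ")" else "]"))
  }
  if (!is.na(x$span_bp)) {
    cat("  span:", format(x$span_bp, big.mark = ","), "bp\n")
  }
  cat("  informative plants:",
      if (length(x$informative)) paste(x$informative, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Does a candidate interval contain a given inter-marker position?
#'
#' Checks whether the gap immediately after `after_marker` (i.e. between
#' it and the next map marker) lies inside the delimited region -- the
#' natural containment check when the true locus position is known, as in
#' simulations.
#'
#' @param interval A `candidate_interval` from [delimit_locus()].
#' @param after_marker Name of the marker immediately left of the
#'   position being tested.
#' @return `TRUE` or `FALSE`.
#' @export
locus_in_interval <- function(interval, after_marker) {
  stopifnot(inherits(interval, "candidate_interval"))
  j <- match(after_marker, interval$map$marker)
  if (is.na(j) || j >= nrow(interval$map)) {
    abort("`after_marker` must be a non-terminal map marker.")
  }
  interval$slots[2 * j]
}

#' Expected recombinant yield of a screening population
#'
#' Expected number of recombinant plants recovered when `n_screened`
#' plants are screened and each carries at least one breakpoint in the
#' target window with probability `r_plant`.
#'
#' @param n_screened Number of plants screened.
#' @param r_plant Per-plant recombination probability in `[0, 1]`.
#' @return Expected recombinant count.
#' @examples
#' recombinant_yield(7424, 308 / 7424)
#' @export
recombinant_yield <- function(n_screened, r_plant) {
  check_count(n_screened, "n_screened")
  check_prob(r_plant, "r_plant")
  n_screened * r_plant
}

#' Estimate the per-plant recombination probability
#'
#' Binomial point estimate and exact Clopper-Pearson interval for the
#' per-plant probability of carrying a breakpoint in the screened window,
#' from the recombinant yield of a screen.
#'
#' @param n_recomb Recombinants observed.
#' @param n_screened Plants screened.
#' @param level Confidence level.
#' @return A tibble with `estimate`, `ci_low`, `ci_high`, `level`.
#' @examples
#' estimate_recomb_rate(308, 7424)
#' @export
estimate_recomb_rate <- function(n_recomb, n_screened, level = 0.95) {
  x <- check_count(n_recomb, "n_recomb")
  n <- check_count(n_screened, "n_screened")
  if (x > n) {
    abort("`n_recomb` cannot exceed `n_screened`.")
  }
  a <- 1 - level
  tibble(
    estimate = x / n,
    ci_low = if (x == 0) 0 else qbeta(a / 2, x, n - x + 1),
    ci_high = if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x),
    level = level
  )
}
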