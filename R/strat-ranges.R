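#' Taxon chronostratigraphic range tables
#'
#' A range table holds, for each taxon, the oldest and youngest possible age
#' of occurrence (in Ma, millions of years before present; larger numbers are
#' older), an optional "known" age range that the taxon must span under any
#' assumption (the interval between occurrences in non-overlapping rock
#' units), an ocean-basin region, and flags controlling how the taxon enters
#' the richness counts. Taxa flagged `count_in = "max_only"` are not tips of
#' the character matrix; they are grafted onto trees by an attachment rule
#' (see [attach_max_only_taxa()]) and enter only the maximum lineage count.
#'
#' Columns:
#' \describe{
#'   \item{taxon}{unique label, used as the tree tip label.}
#'   \item{oldest, youngest}{maximum and minimum possible occurrence age, Ma.}
#'   \item{known_oldest, known_youngest}{optional always-occupied interval,
#'     nested inside `[oldest, youngest]`; `NA` when absent.}
#'   \item{region}{one of `"EastPacific"`, `"WestPacific"`, `"Atlantic"`,
#'     `"Arctic"`.}
#'   \item{analyzed}{`TRUE` if the taxon is a tip of the cladistic matrix.}
#'   \item{count_in}{`"both"` or `"max_only"`.}
#'   \item{attach_anchor, attach_mode}{attachment rule for non-analyzed taxa:
#'     anchor is a tip label or a `+`-separated tip set naming a clade;
#'     mode is `"sister_to_tip"` or `"on_stem_of_clade"`.}
#'   \item{lineage_oldest}{optional override extending the lineage origin
#'     used by the maximum calibration (e.g. a referred specimen older than
#'     any diagnostic material).}
#' }
#'
#' @param x A data frame with the columns above (missing optional columns are
#'   filled with `NA`).
#' @return `validate_taxon_ranges()` returns `x` as a tibble, invisibly
#'   erroring if any row violates the invariants.
#' @export
validate_taxon_ranges <- function(x) {
  x <- as_range_tibble(x)
  if (anyDuplicated(x$taxon)) {
    dup <- unique(x$taxon[duplicated(x$taxon)])
    stop("duplicate taxon name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- function(cond, what) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      stop(what, " for taxon ", paste(x$taxon[cond], collapse = ", "), call. = FALSE)
    }
  }
  bad(!is.finite(x$oldest) | !is.finite(x$youngest), "non-numeric age")
  bad(x$youngest < 0, "negative age")
  bad(x$oldest < x$youngest, "oldest age is younger than youngest age")
  has_known <- !is.na(x$known_oldest) | !is.na(x$known_youngest)
  bad(has_known & (is.na(x$known_oldest) | is.na(x$known_youngest)),
      "incomplete known range")
  bad(has_known &
        !(x$oldest >= x$known_oldest & x$known_oldest >= x$known_youngest &
            x$known_youngest >= x$youngest),
      "known range not nested in the possible range")
  bad(!x$region %in% c("EastPacific", "WestPacific", "Atlantic", "Arctic"),
      "unknown region")
  bad(!x$count_in %in% c("both", "max_only"), "unknown count_in flag")
  bad(x$count_in == "max_only" & x$analyzed,
      "count_in = max_only requires analyzed = FALSE")
  bad(!is.na(x$lineage_oldest) & x$lineage_oldest < x$oldest,
      "lineage_oldest is younger than oldest")
  bad(x$count_in == "max_only" &
        (is.na(x$attach_anchor) | is.na(x$attach_mode)),
      "max_only taxon without an attachment rule")
  bad(!is.na(x$attach_mode) &
        !x$attach_mode %in% c("sister_to_tip", "on_stem_of_clade"),
      "unknown attach_mode")
  x
}

range_cols <- c("taxon", "oldest", "youngest", "known_oldest", "known_youngest",
                "region", "analyzed", "count_in", "attach_anchor",
                "attach_mode", "lineage_oldest")

as_range_tibble <- function(x) {
  x <- tibble::as_tibble(x)
  for (col in range_cols) {
    if (!col %in% names(x)) {
      x[[col]] <- switch(col,
        taxon = , region = , count_in = , attach_anchor = , attach_mode =
          NA_character_,
        analyzed = NA,
        NA_real_
      )
    }
  }
  if (all(is.na(x$analyzed))) x$analyzed <- TRUE
  x$analyzed <- as.logical(x$analyzed)
  x$count_in[is.na(x$count_in)] <- "both"
  num <- c("oldest", "youngest", "known_oldest", "known_youngest", "lineage_oldest")
  for (col in num) x[[col]] <- as.numeric(x[[col]])
  x[range_cols]
}

#' Read and write taxon range tables
#'
#' Tab-separated, one row per taxon, with the columns documented in
#' [validate_taxon_ranges()]. Empty cells mean "absent". `write_taxon_ranges()`
#' and `read_taxon_ranges()` round-trip any valid table.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble of taxon ranges.
#' @export
read_taxon_ranges <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  validate_taxon_ranges(x)
}

#' @rdname read_taxon_ranges
#' @param x A taxon range table.
#' @export
write_taxon_ranges <- function(x, path) {
  x <- validate_taxon_ranges(x)
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Packaged walrus (Odobenidae) chronostratigraphic ranges
#'
#' The 22 valid odobenid taxa with their oldest/youngest possible occurrence
#' ages, transcribed from the published per-taxon chronostratigraphic review.
#' Two taxa known from rock units with non-overlapping ages carry a known
#' range (*Imagotaria downsi* 9.0--8.6 Ma, *Ontocetus emmonsi* 4.9--1.8 Ma);
#' four presumably valid taxa absent from the character matrix are flagged
#' `max_only` with the attachment rule used to place them; the *Valenictus*
#' lineage origin is extended to 5.3 Ma by a referred Purisima Formation
#' specimen. *Nanodobenus arandai* is excluded as too poorly constrained
#' stratigraphically (a 6.5 Ma window from a single site).
#'
#' @return A validated tibble with 22 rows.
#' @export
odobenid_ranges <- function() {
  read_taxon_ranges(system.file("extdata", "appendix1_ranges.tsv",
                                package = "paleorich", mustWork = TRUE))
}

#' Regular time grids
#'
#' Build an ordered sequence of half-open age bins `(old, young]` of equal
#' width covering `(young_edge, old_edge]`. Bin `i` is
#' `(old_edge - (i-1) * step, old_edge - i * step]`: open at its older edge
#' and closed at its younger edge, so an age `a` falls in the bin with
#' `bin_young <= a < bin_old`. The default analysis grid is 17.3 to 0.0 Ma at
#' 0.1 Ma, i.e. 173 bins.
#'
#' @param old_edge,young_edge Older and younger grid edges, Ma.
#' @param step Bin width, Ma.
#' @return A tibble of class `time_grid` with columns `bin`, `bin_old`,
#'   `bin_young`, oldest bin first.
#' @export
make_time_grid <- function(old_edge = 17.3, young_edge = 0.0, step = 0.1) {
  if (!is.finite(step) || step <= 0) stop("step must be positive", call. = FALSE)
  if (!(old_edge > young_edge)) {
    stop("old_edge must be older (larger) than young_edge", call. = FALSE)
  }
  n <- (old_edge - young_edge) / step
  if (abs(n - round(n)) > 1e-9) {
    stop("grid span is not an integral number of steps", call. = FALSE)
  }
  n <- as.integer(round(n))
  grid <- tibble::tibble(
    bin = seq_len(n),
    # rounding snaps edges onto the decimal lattice ages are reported on, so
    # a range endpoint equal to a bin edge compares exactly
    bin_old = round(old_edge - (seq_len(n) - 1L) * step, 9),
    bin_young = round(old_edge - seq_len(n) * step, 9)
  )
  grid$bin_young[n] <- young_edge
  structure(grid, class = c("time_grid", class(grid)),
            old_edge = old_edge, young_edge = young_edge, step = step)
}

#' Chronostratigraphic stage lookup
#'
#' `stage_table()` returns the packaged stage boundaries (current ICS chart,
#' Burdigalian through Holocene); `stage_of()` maps ages to stage names using
#' the same half-open `(older, younger]` convention as the time grid, with the
#' oldest boundary included.
#'
#' @param stages A stage table: columns `stage`, `older`, `younger`,
#'   contiguous and non-overlapping.
#' @return `stage_table()`: a tibble; `stage_of()`: a character vector.
#' @export
stage_table <- function() {
  readr::read_tsv(system.file("extdata", "stage_table.tsv",
                              package = "paleorich", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname stage_table
#' @param age Age(s) in Ma.
#' @export
stage_of <- function(age, stages = stage_table()) {
  top <- max(stages$older)
  if (any(age < 0 | age > top)) {
    stop("age outside the stage table (0 to ", top, " Ma)", call. = FALSE)
  }
  idx <- vapply(age, function(a) {
    which(stages$younger <= a & (a < stages$older | a == top))[1]
  }, integer(1))
  stages$stage[idx]
}
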