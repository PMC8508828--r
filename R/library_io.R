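#' Construct and validate a biomarker library
#'
#' The reporter library is the fixed reference set of GFP-fused yeast strains,
#' each reporting one stress-response protein (ORF) assigned to exactly one of
#' the five stress categories. The study design uses a 74-entry library; the
#' size is not enforced so users can substitute their own strain list.
#'
#' @param entries Data frame with columns `orf`, `gene`, `category`, and
#'   `go_terms` (list column of character vectors, or semicolon-joined
#'   strings).
#' @return A `biomarker_library` tibble with normalized categories.
#' @export
biomarker_library <- function(entries) {
  required <- c("orf", "gene", "category", "go_terms")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    abort(paste0("library table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  entries <- tibble::as_tibble(entries)
  if (anyDuplicated(entries$orf)) {
    dups <- unique(entries$orf[duplicated(entries$orf)])
    abort(paste0("duplicate orf id(s) in library: ",
                 paste(dups, collapse = ", ")))
  }
  entries$category <- normalize_category(entries$category)
  if (!is.list(entries$go_terms)) {
    entries$go_terms <- strsplit(as.character(entries$go_terms), ";", fixed = TRUE)
  }
  entries$go_terms <- lapply(entries$go_terms, function(x) {
    x <- trimws(x)
    unique(x[nzchar(x)])
  })
  class(entries) <- c("biomarker_library", class(tibble::tibble()))
  entries
}

# Case-insensitive normalization onto the five-category vocabulary.
normalize_category <- function(x) {
  canon <- stress_categories()
  idx <- match(tolower(x), tolower(canon))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    abort(paste0("unknown stress category label(s): ",
                 paste(bad, collapse = ", "),
                 "; allowed values: ", paste(canon, collapse = ", ")))
  }
  canon[idx]
}

#' Read a biomarker library table
#'
#' Expects a tab-delimited table with columns `orf`, `gene`, `category`,
#' `go_terms` (semicolon-joined ontology term ids). Category labels are
#' normalized case-insensitively to the five-category vocabulary.
#'
#' @param path Path to the TSV file.
#' @return A [biomarker_library()] object.
#' @export
read_library <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  biomarker_library(tab)
}

#' The synthetic 74-biomarker library shipped with the package
#'
#' The identities of the study's 74 reporter ORFs are not part of this
#' package; this fixture is a synthetic stand-in with plausible yeast
#' stress-response genes partitioned into the five categories, intended for
#' examples and synthetic-data runs. Replace it with your own library via
#' [read_library()].
#'
#' @return A [biomarker_library()] of 74 entries.
#' @export
example_library <- function() {
  path <- system.file("extdata", "biomarker_library_synthetic.tsv",
                      package = "pelitox", mustWork = TRUE)
  read_library(path)
}

#' Construct and validate a plate layout
#'
#' Maps wells to their experimental role. Reporter and vehicle-control wells
#' carry a reporter ORF; internal-control wells carry the housekeeping
#' reporter (PGK1 by default); blank-control wells contain exposure medium
#' (with any test material) but no yeast, so their signal is the optical
#' background that blank subtraction removes.
#'
#' @param wells Data frame with columns `well`, `role`, `orf`, `compound`,
#'   `concentration_mg_L`, `replicate`.
#' @param hk_orf Housekeeping reporter ORF id carried by internal controls.
#' @return A `plate_layout` tibble.
#' @export
plate_layout <- function(wells, hk_orf = "PGK1") {
  required <- c("well", "role", "orf", "compound", "concentration_mg_L", "replicate")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0) {
    abort(paste0("plate map missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  wells <- tibble::as_tibble(wells)
  roles <- c("reporter", "internal_control", "blank_control", "vehicle_control")
  bad_role <- setdiff(unique(wells$role), roles)
  if (length(bad_role) > 0) {
    abort(paste0("unknown well role(s): ", paste(bad_role, collapse = ", "),
                 "; allowed: ", paste(roles, collapse = ", ")))
  }
  if (anyDuplicated(wells$well)) {
    abort("duplicate well ids in plate map")
  }
  blank_with_orf <- wells$role == "blank_control" & !is.na(wells$orf)
  if (any(blank_with_orf)) {
    abort(paste0("blank-control wells must have no orf: ",
                 paste(wells$well[blank_with_orf], collapse = ", ")))
  }
  hk_bad <- wells$role == "internal_control" &
    (is.na(wells$orf) | wells$orf != hk_orf)
  if (any(hk_bad)) {
    abort(paste0("internal-control wells must carry the housekeeping reporter ",
                 hk_orf, ": ", paste(wells$well[hk_bad], collapse = ", ")))
  }
  needs_orf <- wells$role %in% c("reporter", "vehicle_control") & is.na(wells$orf)
  if (any(needs_orf)) {
    abort(paste0("reporter/vehicle wells must name an orf: ",
                 paste(wells$well[needs_orf], collapse = ", ")))
  }
  if (any(!is.na(wells$concentration_mg_L) & wells$concentration_mg_L < 0)) {
    abort("concentrations must be >= 0 mg/L")
  }
  if (any(!is.na(wells$replicate) & (wells$replicate < 1 |
                                     wells$replicate != round(wells$replicate)))) {
    abort("replicate must be a positive integer")
  }
  attr(wells, "hk_orf") <- hk_orf
  class(wells) <- c("plate_layout", class(tibble::tibble()))
  wells
}

#' Read a plate map
#'
#' CSV with columns `well,role,orf,compound,concentration_mg_L,replicate`.
#' Empty fields for `orf`/`compound` denote none (blank wells, vehicle
#' controls).
#'
#' @inheritParams plate_layout
#' @param path Path to the CSV file.
#' @return A [plate_layout()] object.
#' @export
read_plate_map <- function(path, hk_orf = "PGK1") {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           well = readr::col_character(),
                           role = readr::col_character(),
                           orf = readr::col_character(),
                           compound = readr::col_character(),
                           concentration_mg_L = readr::col_double(),
                           replicate = readr::col_integer()
                         ))
  plate_layout(tab, hk_orf = hk_orf)
}

#' Check that a layout's reporter ORFs are covered by a library
#'
#' @param layout A [plate_layout()].
#' @param library A [biomarker_library()].
#' @return `layout`, invisibly, if valid; otherwise an error naming the
#'   unknown ORFs.
#' @export
validate_layout_library <- function(layout, library) {
  reporters <- layout$orf[layout$role %in% c("reporter", "vehicle_control")]
  unknown <- setdiff(unique(reporters), library$orf)
  if (length(unknown) > 0) {
    abort(paste0("layout references ORFs absent from the library: ",
                 paste(unknown, collapse = ", ")))
  }
  invisible(layout)
}

#' Construct a plate time series
#'
#' Holds per-well OD600 and GFP readings on a shared uniform time grid, plus
#' the plate layout. Readings may be non-positive (instrument noise around
#' blank level); downstream normalization applies floors rather than assuming
#' positivity.
#'
#' @param time_min Strictly increasing, uniformly spaced time grid in minutes.
#' @param od,gfp Numeric matrices, wells x time, with rownames equal to well
#'   ids present in `layout`.
#' @param layout A [plate_layout()].
#' @return A `plate_timeseries` object.
#' @export
plate_timeseries <- function(time_min, od, gfp, layout) {
  time_min <- as.numeric(time_min)
  check_uniform_grid(time_min)
  od <- as.matrix(od)
  gfp <- as.matrix(gfp)
  if (!identical(dim(od), dim(gfp))) {
    abort("od and gfp matrices must share dimensions")
  }
  if (ncol(od) != length(time_min)) {
    abort("matrix columns must match the time grid length")
  }
  if (is.null(rownames(od)) || !identical(rownames(od), rownames(gfp))) {
    abort("od and gfp must carry identical well rownames")
  }
  if (!all(is.finite(od)) || !all(is.finite(gfp))) {
    abort("all OD and GFP readings must be finite")
  }
  extra <- setdiff(rownames(od), layout$well)
  if (length(extra) > 0) {
    abort(paste0("wells present in data but absent from plate map: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  structure(
    list(time_min = time_min, od = od, gfp = gfp, layout = layout),
    class = "plate_timeseries"
  )
}

check_uniform_grid <- function(time_min, tol = 1e-8) {
  if (length(time_min) < 2L) abort("time grid needs at least 2 points")
  if (any(diff(time_min) <= 0)) abort("time grid must be strictly increasing")
  steps <- diff(time_min)
  ref <- stats::median(steps)
  bad <- which(abs(steps - ref) > tol * max(1, ref))
  if (length(bad) > 0) {
    offending <- time_min[bad + 1L]
    abort(paste0("nonuniform time grid; offending time(s): ",
                 paste(offending, collapse = ", "), " min"))
  }
  invisible(time_min)
}

#' @export
print.plate_timeseries <- function(x, ...) {
  cat(sprintf("<plate_timeseries> %d wells x %d timepoints (%.0f-%.0f min)\n",
              nrow(x$od), length(x$time_min), min(x$time_min), max(x$time_min)))
  cat("roles: ",
      paste(sprintf("%s=%d", names(table(x$layout$role)), table(x$layout$role)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reader dialect for plate exports
#'
#' The canonical interchange format is the long-form delimited table
#' (`well,time_min,channel,value`); wide form (one row per well x channel,
#' one column per time) is supported as a reader dialect.
#'
#' @param format `"long"` or `"wide"`.
#' @param delim Field delimiter.
#' @param channels Named character vector mapping the internal channels
#'   `od`/`gfp` to the labels used in the file.
#' @return A dialect description list.
#' @export
plate_dialect <- function(format = c("long", "wide"), delim = ",",
                          channels = c(od = "OD600", gfp = "GFP")) {
  format <- match.arg(format)
  stopifnot(all(c("od", "gfp") %in% names(channels)))
  list(format = format, delim = delim, channels = channels)
}

#' Read a plate-reader export
#'
#' Long form: columns `well,time_min,channel,value`, channel labels per the
#' dialect (default `OD600`/`GFP`). Wide form: columns `well,channel` then one
#' column per timepoint, named by minutes. Every (well, time, channel) cell
#' must be present: missing cells are an error, never an imputation.
#'
#' @param path Path to the delimited text export.
#' @param layout A [plate_layout()] covering every well in the file.
#' @param dialect A [plate_dialect()].
#' @return A [plate_timeseries()].
#' @export
read_plate_export <- function(path, layout, dialect = plate_dialect()) {
  # values parsed via strtod (correctly rounded) for a lossless round trip
  tab <- readr::read_delim(path, delim = dialect$delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (dialect$format == "wide") {
    time_cols <- setdiff(names(tab), c("well", "channel"))
    tab <- tidyr::pivot_longer(tab, cols = dplyr::all_of(time_cols),
                               names_to = "time_min", values_to = "value")
  }
  tab$time_min <- as.numeric(tab$time_min)
  tab$value <- as.numeric(tab$value)
  required <- c("well", "time_min", "channel", "value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("plate export missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  known <- unname(dialect$channels)
  bad_chan <- setdiff(unique(tab$channel), known)
  if (length(bad_chan) > 0) {
    abort(paste0("unknown channel label(s): ", paste(bad_chan, collapse = ", "),
                 "; expected: ", paste(known, collapse = ", ")))
  }
  time_min <- sort(unique(tab$time_min))
  check_uniform_grid(time_min)
  wells <- unique(tab$well)
  extra <- setdiff(wells, layout$well)
  if (length(extra) > 0) {
    abort(paste0("wells present in data but absent from plate map: ",
                 paste(head(extra, 5), collapse = ", ")))
  }

  channel_matrix <- function(label) {
    sub <- tab[tab$channel == label, c("well", "time_min", "value")]
    m <- matrix(NA_real_, nrow = length(wells), ncol = length(time_min),
                dimnames = list(wells, NULL))
    m[cbind(match(sub$well, wells), match(sub$time_min, time_min))] <- sub$value
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, , drop = TRUE]
      abort(sprintf("missing %s reading for well %s at time %g min",
                    label, wells[idx[1]], time_min[idx[2]]))
    }
    m
  }
  od <- channel_matrix(dialect$channels[["od"]])
  gfp <- channel_matrix(dialect$channels[["gfp"]])
  plate_timeseries(time_min, od, gfp,
                   layout[layout$well %in% wells, , drop = FALSE])
}

#' Write a plate time series as a delimited export
#'
#' Inverse of [read_plate_export()]; writing then reading reproduces the
#' matrices exactly (readr writes shortest round-trippable doubles).
#'
#' @param pts A [plate_timeseries()].
#' @param path Output file path.
#' @param dialect A [plate_dialect()].
#' @return `path`, invisibly.
#' @export
write_plate_export <- function(pts, path, dialect = plate_dialect()) {
  long <- plate_long_table(pts, dialect)
  # 17 significant digits round-trip IEEE doubles exactly
  long$value <- sprintf("%.17g", long$value)
  if (dialect$format == "wide") {
    wide <- tidyr::pivot_wider(long, names_from = "time_min",
                               values_from = "value")
    readr::write_delim(wide, path, delim = dialect$delim)
  } else {
    readr::write_delim(long, path, delim = dialect$delim)
  }
  invisible(path)
}

plate_long_table <- function(pts, dialect = plate_dialect()) {
  wells <- rownames(pts$od)
  nt <- length(pts$time_min)
  one <- function(mat, label) {
    tibble::tibble(
      well = rep(wells, each = nt),
      time_min = rep(pts$time_min, times = length(wells)),
      channel = label,
      value = as.vector(t(mat))
    )
  }
  dplyr::bind_rows(one(pts$od, dialect$channels[["od"]]),
                   one(pts$gfp, dialect$channels[["gfp"]]))
}

#' Write a plate map CSV
#'
#' @param layout A [plate_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(layout, path) {
  readr::write_csv(as.data.frame(layout), path, na = "")
  invisible(path)
}

#' Read an ontology term map
#'
#' Two-column tab-delimited `term,orf` pairs (gene-association style); terms
#' are treated as flat sets (no ontology-graph propagation).
#'
#' @param path Path to the TSV file.
#' @return Named list mapping term id to a character vector of ORFs.
#' @export
read_term_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("term", "orf") %in% names(tab))) {
    abort("term map must have columns term, orf")
  }
  split(tab$orf, tab$term)
}

#' Build a term map from a library's annotations
#'
#' @param library A [biomarker_library()].
#' @return Named list mapping term id to ORFs, as in [read_term_map()].
#' @export
term_map_from_library <- function(library) {
  pairs <- tidyr::unnest(
    tibble::tibble(orf = library$orf, term = library$go_terms),
    cols = "term"
  )
  split(pairs$orf, pairs$term)
}
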