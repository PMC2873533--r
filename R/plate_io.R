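#' Construct a single amplification run
#'
#' An `amp_run` holds one well's cycle-indexed fluorescence readings plus
#' plate metadata. Cycles must be consecutive integers starting anywhere;
#' fluorescence must be finite and the same length. Standards must carry
#' their known input amount (`log10_input`).
#'
#' @param run_id character scalar identifying the well/run.
#' @param cycles integer vector of cycle numbers, strictly increasing and
#'   consecutive.
#' @param fluorescence numeric vector of readings (arbitrary fluorescence
#'   units), same length as `cycles`.
#' @param role `"standard"` or `"test"`.
#' @param log10_input log10 of expected template copies (required for
#'   standards), or `NA`.
#' @param inhibitor inhibitor name or `NA`.
#' @param inhibitor_conc inhibitor concentration (mg/mL) or `NA`.
#' @return An object of class `amp_run`.
#' @export
amp_run <- function(run_id, cycles, fluorescence, role = "test",
                    log10_input = NA_real_, inhibitor = NA_character_,
                    inhibitor_conc = NA_real_) {
  run_id <- as.character(run_id)
  cycles <- as.integer(cycles)
  fluorescence <- as.numeric(fluorescence)
  stopifnot(length(run_id) == 1L, !is.na(run_id))
  if (length(cycles) != length(fluorescence))
    sod_error("sod_bad_run", sprintf(
      "run '%s': %d cycles but %d fluorescence readings",
      run_id, length(cycles), length(fluorescence)))
  if (length(cycles) < 2L || any(diff(cycles) != 1L)) {
    gap <- if (length(cycles) >= 2L) cycles[which(diff(cycles) != 1L)[1]] else NA
    sod_error("sod_bad_run", sprintf(
      "run '%s': cycles must be consecutive integers (gap after cycle %s)",
      run_id, gap))
  }
  if (any(!is.finite(fluorescence)))
    sod_error("sod_bad_run", sprintf(
      "run '%s': non-finite fluorescence at cycle %d",
      run_id, cycles[which(!is.finite(fluorescence))[1]]))
  role <- match.arg(role, c("standard", "test"))
  if (role == "standard" && is.na(log10_input))
    sod_error("sod_bad_run", sprintf(
      "run '%s': role 'standard' requires log10_input", run_id))
  structure(
    list(run_id = run_id, cycles = cycles, fluorescence = fluorescence,
         role = role, log10_input = as.numeric(log10_input),
         inhibitor = as.character(inhibitor),
         inhibitor_conc = as.numeric(inhibitor_conc)),
    class = "amp_run")
}

#' @export
print.amp_run <- function(x, ...) {
  cat(sprintf("<amp_run '%s'> %d cycles, role=%s, log10_input=%s\n",
              x$run_id, length(x$cycles), x$role,
              ifelse(is.na(x$log10_input), "NA",
                     format(x$log10_input, digits = 4))))
  invisible(x)
}

new_plate <- function(runs) {
  names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  structure(runs, class = "amp_plate")
}

#' @export
print.amp_plate <- function(x, ...) {
  roles <- vapply(x, `[[`, character(1), "role")
  cat(sprintf("<amp_plate> %d runs (%d standard, %d test)\n",
              length(x), sum(roles == "standard"), sum(roles == "test")))
  invisible(x)
}

#' @export
`[.amp_plate` <- function(x, i) new_plate(unclass(x)[i])

#' @export
c.amp_plate <- function(...) {
  runs <- unlist(lapply(list(...), unclass), recursive = FALSE)
  ids <- vapply(runs, `[[`, character(1), "run_id")
  if (anyDuplicated(ids))
    sod_error("sod_bad_run", sprintf("duplicate run_id '%s' when combining plates",
                                     ids[duplicated(ids)][1]))
  new_plate(runs)
}

#' @export
as.data.frame.amp_plate <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(r)
    data.frame(run_id = r$run_id, cycle = r$cycles,
               fluorescence = r$fluorescence, row.names = NULL)))
}

#' Read fluorescence tables into a plate of amplification runs
#'
#' Two CSV layouts are supported. Long: columns `run_id,cycle,fluorescence`.
#' Wide: a `cycle` column plus one numeric column per run (column name =
#' run id). Input is assumed background-subtracted; set `baseline = TRUE`
#' to subtract the mean of the first `baseline_cycles` readings of each run
#' (the Richards background term absorbs residual baseline either way).
#'
#' @param path CSV file path.
#' @param layout `"long"` or `"wide"`.
#' @param baseline subtract an early-cycle baseline estimate per run?
#' @param baseline_cycles number of initial cycles averaged for the baseline.
#' @return An `amp_plate` (list of [amp_run()]); metadata fields are left
#'   missing until [join_metadata()] is applied.
#' @export
read_fluorescence <- function(path, layout = c("long", "wide"),
                              baseline = FALSE, baseline_cycles = 5L) {
  layout <- match.arg(layout)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "long") {
    need <- c("run_id", "cycle", "fluorescence")
    if (!all(need %in% names(tab)))
      sod_error("sod_bad_table", sprintf(
        "long layout needs columns %s; found: %s",
        paste(need, collapse = ", "), paste(names(tab), collapse = ", ")))
    if (!is.numeric(tab$fluorescence)) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab$fluorescence))))[1]
      sod_error("sod_bad_table", sprintf(
        "non-numeric fluorescence at row %d ('%s')", bad,
        tab$fluorescence[bad]))
    }
    key <- paste(tab$run_id, tab$cycle)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      sod_error("sod_bad_table", sprintf(
        "duplicate (run_id, cycle) pair: (%s)", gsub(" ", ", ", d)))
    }
    runs <- lapply(split(tab, tab$run_id), function(g) {
      g <- g[order(g$cycle), ]
      amp_run(g$run_id[1], g$cycle, g$fluorescence)
    })
  } else {
    if (names(tab)[1] != "cycle")
      sod_error("sod_bad_table", "wide layout: first column must be 'cycle'")
    ids <- names(tab)[-1]
    if (length(ids) == 0L)
      sod_error("sod_bad_table", "wide layout: no run columns found")
    runs <- lapply(ids, function(id) {
      f <- tab[[id]]
      if (!is.numeric(f)) {
        bad <- which(is.na(suppressWarnings(as.numeric(f))))[1]
        sod_error("sod_bad_table", sprintf(
          "non-numeric fluorescence for run '%s' at row %d ('%s')",
          id, bad, f[bad]))
      }
      ord <- order(tab$cycle)
      amp_run(id, tab$cycle[ord], f[ord])
    })
  }
  if (baseline) {
    runs <- lapply(runs, function(r) {
      k <- min(baseline_cycles, length(r$fluorescence))
      r$fluorescence <- r$fluorescence - mean(r$fluorescence[seq_len(k)])
      r
    })
  }
  new_plate(runs)
}

#' Write a plate's fluorescence back to CSV
#'
#' Inverse of [read_fluorescence()]; round-trips values up to float
#' formatting.
#'
#' @param plate an `amp_plate`.
#' @param path output CSV path.
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_fluorescence <- function(plate, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  long <- as.data.frame(plate)
  if (layout == "long") {
    write.csv(long, path, row.names = FALSE, quote = FALSE)
  } else {
    cyc <- sort(unique(long$cycle))
    wide <- data.frame(cycle = cyc)
    for (id in names(plate)) {
      r <- plate[[id]]
      if (!identical(as.integer(cyc), r$cycles))
        sod_error("sod_bad_table",
                  "wide layout requires all runs to share one cycle grid")
      wide[[id]] <- r$fluorescence
    }
    write.csv(wide, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Join plate metadata onto runs
#'
#' Metadata columns: `run_id`, `role`, and optionally `log10_input`,
#' `inhibitor`, `inhibitor_conc`. Runs absent from the table default to
#' `role = "test"` with missing annotations (a message reports how many).
#' Metadata rows that match no run raise a warning. A standard lacking
#' `log10_input` is rejected.
#'
#' @param plate an `amp_plate` from [read_fluorescence()].
#' @param meta data frame of per-run metadata (e.g. read from CSV).
#' @return The annotated `amp_plate`.
#' @export
join_metadata <- function(plate, meta) {
  stopifnot(inherits(plate, "amp_plate"), is.data.frame(meta))
  if (nrow(meta) > 0 && !all(c("run_id", "role") %in% names(meta)))
    sod_error("sod_bad_table", "metadata needs columns run_id and role")
  extra <- setdiff(meta$run_id, names(plate))
  if (length(extra))
    warning(sprintf("metadata run_id(s) not found among runs: %s",
                    paste(extra, collapse = ", ")))
  opt <- function(col, i, default) {
    if (col %in% names(meta) && !is.na(meta[[col]][i])) meta[[col]][i]
    else default
  }
  n_default <- 0L
  runs <- lapply(unclass(plate), function(r) {
    i <- match(r$run_id, meta$run_id)
    if (is.na(i)) {
      n_default <<- n_default + 1L
      return(r)  # constructor default: test, annotations missing
    }
    amp_run(r$run_id, r$cycles, r$fluorescence,
            role = as.character(meta$role[i]),
            log10_input = opt("log10_input", i, NA_real_),
            inhibitor = opt("inhibitor", i, NA_character_),
            inhibitor_conc = opt("inhibitor_conc", i, NA_real_))
  })
  if (n_default > 0L)
    message(sprintf("%d run(s) absent from metadata; defaulted to role=test",
                    n_default))
  new_plate(runs)
}

#' Read a metadata CSV
#'
#' Convenience wrapper: `run_id,role,log10_input,inhibitor,inhibitor_conc`
#' with empty cells for missing values.
#'
#' @param path CSV path.
#' @return data frame suitable for [join_metadata()].
#' @export
read_metadata <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(run_id = "character"))
}
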