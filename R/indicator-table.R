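#' Unit-by-indicator tables for stratified sampling design
#'
#' An `indicator_table` holds one row per geographic unit (district), the
#' province each unit belongs to, its population, and a numeric matrix of
#' indicator values. Each indicator carries metadata: which conceptual
#' factor it measures (demand, structure or outcome) and its native
#' geographic level (district or province). Province-native indicators hold
#' the province's value repeated across its districts once broadcast.
#'
#' @param unit_id character vector of unique unit (district) identifiers.
#' @param province_id character vector of province identifiers, one per unit.
#' @param population positive numeric vector of unit populations (persons).
#' @param values numeric matrix, units x indicators; may contain `NA` before
#'   broadcasting/imputation.
#' @param meta data frame with columns `name`, `factor`
#'   (`"demand"`, `"structure"` or `"outcome"`) and `native_level`
#'   (`"district"` or `"province"`), one row per indicator, in column order
#'   of `values`.
#' @param standardized logical; `TRUE` once columns have been centred and
#'   scaled by [standardize()].
#'
#' @return An object of class `indicator_table`: a list with elements
#'   `unit_id`, `province_id`, `population`, `values`, `meta`,
#'   `standardized`.
#' @seealso [read_indicator_table()], [broadcast_province_values()],
#'   [standardize()]
#' @export
indicator_table <- function(unit_id, province_id, population, values, meta,
                            standardized = FALSE) {
  unit_id <- as.character(unit_id)
  province_id <- as.character(province_id)
  population <- as.numeric(population)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyDuplicated(unit_id)) {
    dup <- unique(unit_id[duplicated(unit_id)])
    stop("duplicate unit_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  n <- length(unit_id)
  if (length(province_id) != n || length(population) != n ||
      nrow(values) != n) {
    stop("unit_id, province_id, population and rows of values must align",
         call. = FALSE)
  }
  if (any(is.na(province_id)) || any(!nzchar(province_id))) {
    stop("every unit needs a province_id", call. = FALSE)
  }
  if (any(is.na(population)) || any(population <= 0)) {
    stop("population must be positive for all units", call. = FALSE)
  }
  meta <- validate_indicator_meta(meta, colnames(values))
  colnames(values) <- meta$name
  rownames(values) <- unit_id
  structure(
    list(unit_id = unit_id, province_id = province_id,
         population = population, values = values, meta = meta,
         standardized = isTRUE(standardized)),
    class = "indicator_table"
  )
}

validate_indicator_meta <- function(meta, value_names = NULL) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("name", "factor", "native_level")
  if (!all(req %in% names(meta))) {
    stop("indicator metadata needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[, req]
  meta$name <- as.character(meta$name)
  bad_f <- setdiff(meta$factor, c("demand", "structure", "outcome"))
  if (length(bad_f)) {
    stop("unknown indicator factor: ", paste(bad_f, collapse = ", "),
         call. = FALSE)
  }
  bad_l <- setdiff(meta$native_level, c("district", "province"))
  if (length(bad_l)) {
    stop("unknown native_level: ", paste(bad_l, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(value_names)) {
    if (is.null(value_names)) value_names <- meta$name
    extra <- setdiff(value_names, meta$name)
    missing <- setdiff(meta$name, value_names)
    if (length(extra) || length(missing)) {
      stop("indicator columns and metadata disagree",
           if (length(extra)) paste0("; unknown indicator name: ",
                                     paste(extra, collapse = ", ")),
           if (length(missing)) paste0("; metadata without column: ",
                                       paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    # keep meta in column order
    meta <- meta[match(value_names, meta$name), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' @export
print.indicator_table <- function(x, ...) {
  cat(sprintf("indicator_table: %d units, %d provinces, %d indicators%s\n",
              length(x$unit_id), length(unique(x$province_id)),
              ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  n_miss <- sum(is.na(x$values))
  if (n_miss > 0) cat(sprintf("  %d missing cells pending imputation\n",
                              n_miss))
  invisible(x)
}

#' @export
dim.indicator_table <- function(x) dim(x$values)

#' Read a unit-by-indicator CSV into an `indicator_table`
#'
#' The CSV must have a header row with columns `unit_id`, `province_id`,
#' `population`, followed by one numeric column per indicator. Indicator
#' metadata is supplied either as a data frame or as the path to a YAML file
#' mapping each indicator name to its `factor` and `native_level`.
#'
#' Missing cells are permitted only for province-native indicators (to be
#' filled by [broadcast_province_values()]) or where a district-native value
#' is genuinely unavailable and will fall back to the province value.
#'
#' @param path path to the CSV file (comma-separated, UTF-8, `.` decimal).
#' @param meta indicator metadata: a data frame with columns `name`,
#'   `factor`, `native_level`, or the path to a YAML file whose top-level
#'   keys are indicator names with `factor` and `native_level` entries.
#' @return An [indicator_table()] with raw (unstandardized) values.
#' @export
read_indicator_table <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(meta) && length(meta) == 1L) meta <- read_indicator_meta(meta)
  meta <- validate_indicator_meta(meta)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  id_cols <- c("unit_id", "province_id", "population")
  if (!all(id_cols %in% names(df))) {
    stop("CSV must contain columns unit_id, province_id, population",
         call. = FALSE)
  }
  ind_cols <- setdiff(names(df), id_cols)
  extra <- setdiff(ind_cols, meta$name)
  if (length(extra)) {
    stop("unknown indicator name in CSV header: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(meta$name, ind_cols)
  if (length(absent)) {
    stop("indicator missing from CSV: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  pop <- suppressWarnings(as.numeric(df$population))
  if (any(is.na(pop)) || any(pop <= 0)) {
    stop("population column must parse as positive numbers", call. = FALSE)
  }
  values <- matrix(NA_real_, nrow(df), length(ind_cols),
                   dimnames = list(df$unit_id, ind_cols))
  for (j in ind_cols) {
    raw <- df[[j]]
    blank <- is.na(raw) | raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   raw[bad[1]], j, bad[1]), call. = FALSE)
    }
    values[, j] <- num
  }
  values <- values[, meta$name, drop = FALSE]
  indicator_table(df$unit_id, df$province_id, pop, values, meta)
}

#' Read indicator metadata from a YAML file
#'
#' @param path YAML file whose top-level keys are indicator names, each with
#'   `factor` and `native_level` entries.
#' @return Data frame with columns `name`, `factor`, `native_level`.
#' @export
read_indicator_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  meta <- data.frame(
    name = names(y),
    factor = vapply(y, function(e) as.character(e$factor), ""),
    native_level = vapply(y, function(e) as.character(e$native_level), ""),
    stringsAsFactors = FALSE
  )
  validate_indicator_meta(meta)
}

#' Write an `indicator_table` (and optionally its metadata) to CSV/YAML
#'
#' Values are written as decimal text with 12 significant digits, which
#' round-trips bit-identically through [read_indicator_table()] for values
#' that are representable at that precision.
#'
#' @param table an [indicator_table()].
#' @param path output CSV path.
#' @param meta_path optional output path for a YAML metadata companion file.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(table, path, meta_path = NULL) {
  stopifnot(inherits(table, "indicator_table"))
  vals <- apply(table$values, 2, function(x) {
    out <- sprintf("%.12g", x)
    out[is.na(x)] <- ""
    out
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(table$values))
  df <- data.frame(unit_id = table$unit_id, province_id = table$province_id,
                   population = sprintf("%.12g", table$population),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  names(df) <- c("unit_id", "province_id", "population", colnames(table$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    y <- lapply(seq_len(nrow(table$meta)), function(i) {
      list(factor = table$meta$factor[i],
           native_level = table$meta$native_level[i])
    })
    names(y) <- table$meta$name
    yaml::write_yaml(y, meta_path)
  }
  invisible(path)
}

#' Broadcast province-level values to districts and fill missing cells
#'
#' Province-native indicators are observed once per province; each district
#' inherits its province's value. District-native cells that are missing may
#' also fall back to the province value when one is supplied, mirroring the
#' practice of substituting province-level information where district-level
#' data are unavailable.
#'
#' @param table an [indicator_table()].
#' @param province_values a named list: `province_values[[province]][[indicator]]`
#'   gives the province's value, or a data frame with columns `province_id`,
#'   `indicator`, `value`.
#' @return The table with all province-native cells set to their province's
#'   value and no missing cells remaining.
#' @export
broadcast_province_values <- function(table, province_values = NULL) {
  stopifnot(inherits(table, "indicator_table"))
  pv <- normalize_province_values(province_values)
  values <- table$values
  prov <- table$province_id
  for (j in seq_len(ncol(values))) {
    ind <- table$meta$name[j]
    prov_native <- table$meta$native_level[j] == "province"
    if (prov_native) {
      need <- unique(prov)
      have <- !is.na(vapply(need, function(p) pv_lookup(pv, p, ind), 0))
      if (any(!have)) {
        # fall back to the value already carried by the province's districts
        carried <- vapply(need, function(p) {
          v <- unique(values[prov == p, j])
          v <- v[!is.na(v)]
          if (length(v) == 1L) v else NA_real_
        }, 0)
        miss <- need[!have & is.na(carried)]
        if (length(miss)) {
          stop("no province value for province(s) ",
               paste(miss, collapse = ", "), " on indicator '", ind, "'",
               call. = FALSE)
        }
        for (p in need) {
          v <- pv_lookup(pv, p, ind)
          if (is.na(v)) v <- carried[p]
          values[prov == p, j] <- v
        }
      } else {
        for (p in need) values[prov == p, j] <- pv_lookup(pv, p, ind)
      }
    } else if (anyNA(values[, j])) {
      miss_rows <- which(is.na(values[, j]))
      for (i in miss_rows) {
        v <- pv_lookup(pv, prov[i], ind)
        if (is.na(v)) {
          stop("missing district value for unit '", table$unit_id[i],
               "', indicator '", ind,
               "' and no province fallback for province '", prov[i], "'",
               call. = FALSE)
        }
        values[i, j] <- v
      }
    }
  }
  table$values <- values
  table
}

normalize_province_values <- function(province_values) {
  if (is.null(province_values)) return(list())
  if (is.data.frame(province_values)) {
    req <- c("province_id", "indicator", "value")
    stopifnot(all(req %in% names(province_values)))
    out <- list()
    for (i in seq_len(nrow(province_values))) {
      p <- as.character(province_values$province_id[i])
      ind <- as.character(province_values$indicator[i])
      out[[p]][[ind]] <- as.numeric(province_values$value[i])
    }
    return(out)
  }
  province_values
}

pv_lookup <- function(pv, province, indicator) {
  v <- pv[[province]][[indicator]]
  if (is.null(v)) NA_real_ else as.numeric(v)
}

#' Standardize indicator columns to mean zero and unit sample variance
#'
#' Each column is transformed to `(x - mean(x)) / sd(x)` with the sample
#' standard deviation (denominator `n - 1`). Constant columns cannot be
#' scaled and are mapped to all zeros with a warning. Standardizing an
#' already-standardized table is a no-op up to floating-point error.
#' Downstream Euclidean-distance computations (Hopkins, clustering, validity
#' indices) expect standardized input so that no indicator dominates purely
#' through its measurement scale.
#'
#' @param table an [indicator_table()] with no missing values.
#' @return The table with scaled values and `standardized = TRUE`.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  if (anyNA(table$values)) {
    stop("cannot standardize: missing values remain (broadcast first)",
         call. = FALSE)
  }
  if (nrow(table$values) < 2L) {
    stop("cannot standardize fewer than 2 units", call. = FALSE)
  }
  v <- table$values
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning("constant column(s) mapped to zero: ",
            paste(colnames(v)[const], collapse = ", "), call. = FALSE)
    sdv[const] <- 1
  }
  v <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  v[, const] <- 0
  table$values <- v
  table$standardized <- TRUE
  table
}
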