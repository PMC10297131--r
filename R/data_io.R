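#' Read a CKD table in the UCI dialect (ARFF or CSV)
#'
#' Parses either the original ARFF-style file distributed by the UCI
#' repository or a CSV export with a header row. The UCI file is dirty:
#' cells may carry stray tabs and whitespace, and `?` (or an empty cell)
#' marks a missing value; all of these are tolerated. Binary categorical
#' strings are coded to 0/1 via the schema; the class column is removed
#' from the feature matrix and coded ckd -> 1, notckd -> 0.
#'
#' @param path path to the data file.
#' @param dialect `"arff"` or `"csv"`; default guesses from the extension.
#' @param schema feature schema, default [ckd_schema()].
#' @param provenance provenance tag stored on the result.
#' @return a [ckd_dataset()].
#' @export
read_ckd_file <- function(path, dialect = c("auto", "arff", "csv"),
                          schema = ckd_schema(), provenance = "uci") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  lines <- readLines(path, warn = FALSE)
  if (dialect == "arff") {
    parsed <- parse_arff_lines(lines)
  } else {
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("CSV file needs a header and at least one row")
    header <- strip_cell(strsplit(lines[[1]], ",", fixed = TRUE)[[1]])
    parsed <- list(columns = header, rows = lines[-1])
  }
  decode_ckd_rows(parsed$columns, parsed$rows, schema, provenance)
}

# ARFF: @attribute lines give column order; everything after @data is rows.
parse_arff_lines <- function(lines) {
  low <- tolower(trimws(lines))
  attr_idx <- grep("^@attribute", low)
  data_idx <- grep("^@data", low)
  if (length(data_idx) != 1L) stop("ARFF file must contain a single @data line")
  columns <- vapply(lines[attr_idx], function(l) {
    # token after '@attribute', possibly quoted
    m <- regmatches(l, regexec("^\\s*@attribute\\s+['\"]?([^'\"[:space:]]+)",
                               l, ignore.case = TRUE))[[1]]
    if (length(m) < 2L) stop("unparseable @attribute line: ", l)
    m[2]
  }, character(1), USE.NAMES = FALSE)
  rows <- lines[seq.int(data_idx + 1L, length(lines))]
  rows <- rows[nzchar(gsub("[\\s,]", "", rows, perl = TRUE))]
  list(columns = columns, rows = rows)
}

strip_cell <- function(x) gsub("^[\\s\t]+|[\\s\t]+$", "", x, perl = TRUE)

decode_ckd_rows <- function(columns, rows, schema, provenance) {
  columns <- tolower(strip_cell(columns))
  class_aliases <- c("class", "classification")
  known <- c(schema$names, class_aliases)
  bad <- setdiff(columns, known)
  if (length(bad))
    stop("unknown column name(s): ", paste(bad, collapse = ", "))
  if (!any(columns %in% class_aliases)) stop("no class column found")
  missing_cols <- setdiff(schema$names, columns)
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))

  cells <- lapply(rows, function(r) strip_cell(strsplit(r, ",", fixed = TRUE)[[1]]))
  nc <- length(columns)
  cells <- lapply(cells, function(x) { length(x) <- nc; x })
  M <- do.call(rbind, cells)  # character matrix, rows x columns
  colnames(M) <- columns
  n <- nrow(M)

  is_missing <- function(v) is.na(v) | v == "?" | v == ""
  cls_raw <- tolower(M[, which(columns %in% class_aliases)[1]])
  y <- ifelse(cls_raw == "ckd", 1L, ifelse(cls_raw == "notckd", 0L, NA_integer_))
  if (anyNA(y))
    stop("unparseable class label at row ", which(is.na(y))[1],
         " (expected 'ckd' or 'notckd')")

  d <- length(schema$names)
  X <- matrix(NA_real_, n, d, dimnames = list(NULL, schema$names))
  mask <- matrix(FALSE, n, d, dimnames = list(NULL, schema$names))
  binary <- schema_binary_features(schema)
  for (f in schema$names) {
    v <- M[, f]
    miss <- is_missing(v)
    mask[, f] <- miss
    obs <- which(!miss)
    if (!length(obs)) next
    if (f %in% binary) {
      codes <- schema$categorical_levels[[f]]
      hit <- match(tolower(v[obs]), names(codes))
      if (anyNA(hit)) {
        r <- obs[which(is.na(hit))[1]]
        stop("unknown level '", v[r], "' for '", f, "' at row ", r,
             "; allowed: ", paste(names(codes), collapse = ", "))
      }
      X[obs, f] <- unname(codes[hit])
    } else {
      num <- suppressWarnings(as.numeric(v[obs]))
      if (anyNA(num)) {
        r <- obs[which(is.na(num))[1]]
        stop("unparseable numeric cell '", M[r, f], "' at row ", r,
             ", column '", f, "'")
      }
      X[obs, f] <- num
    }
  }
  ckd_dataset(X, mask, y, schema, provenance)
}

#' Write a dataset as CSV in the package dialect
#'
#' Header row is the schema names plus `class`; missing cells are written
#' as `?`; binary categorical codes are written back as their level strings;
#' numerics are printed with enough digits to round-trip exactly.
#'
#' @param ds a [ckd_dataset()].
#' @param path output path.
#' @export
write_ckd_csv <- function(ds, path) {
  schema <- ds$schema
  binary <- schema_binary_features(schema)
  n <- nrow(ds$X)
  cols <- lapply(schema$names, function(f) {
    v <- ds$X[, f]
    out <- character(n)
    obs <- !ds$mask[, f]
    if (f %in% binary) {
      codes <- schema$categorical_levels[[f]]
      out[obs] <- names(codes)[match(v[obs], codes)]
    } else {
      out[obs] <- vapply(v[obs], num_to_str, character(1))
    }
    out[!obs] <- "?"
    out
  })
  cols <- c(cols, list(ifelse(ds$y == 1L, "ckd", "notckd")))
  body <- do.call(paste, c(cols, sep = ","))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(paste(c(schema$names, "class"), collapse = ","), body), con)
  invisible(NULL)
}

# shortest decimal string that reads back to the identical double
num_to_str <- function(x) {
  for (dg in 1:17) {
    s <- sprintf("%.*g", dg, x)
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

#' Specification for the synthetic CKD-like generator
#'
#' Defaults encode the class-conditional spreads reported for the real
#' cohort: non-CKD hemoglobin concentrated in 12.5-17.5 versus CKD dispersed
#' over 5-17.5, CKD blood pressure spanning 60-100, CKD age concentrated in
#' 50-70 versus non-CKD 20-80, albumin below 1 for non-CKD but up to 5 for
#' CKD, blood glucose 50-150 for non-CKD, packed cell volume and red-cell
#' counts lower under CKD, comparable sodium/potassium, and CKD-enriched
#' hypertension/diabetes rates. Features without a reported spread get a
#' unit-variance normal with a class mean-shift `delta`.
#'
#' @param n_per_class patients generated per class (total n = 2 * n_per_class).
#' @param missing_rate per-cell independent masking probability.
#' @param delta class mean-shift for features with no reported spread.
#' @param seed integer RNG seed.
#' @param numeric_dists,binary_rates optional overrides; same structure as
#'   the defaults (per feature, per class `ckd` / `notckd`).
#' @return an object of class `ckd_synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 200L, missing_rate = 0,
                           delta = 1.0, seed = 1L,
                           numeric_dists = NULL, binary_rates = NULL) {
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1L) stop("n_per_class must be >= 1")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  tn <- function(low, high) list(dist = "truncnorm", low = low, high = high,
                                 mean = (low + high) / 2, sd = (high - low) / 4)
  sh <- function(mu) list(dist = "normal", mean = mu, sd = 1)
  dists <- list(
    age  = list(notckd = tn(20, 80),   ckd = tn(50, 70)),
    bp   = list(notckd = tn(60, 80),   ckd = tn(60, 100)),
    sg   = list(notckd = sh(0),        ckd = sh(delta)),
    al   = list(notckd = tn(0, 1),     ckd = tn(0, 5)),
    su   = list(notckd = sh(0),        ckd = sh(delta)),
    bgr  = list(notckd = tn(50, 150),  ckd = tn(50, 400)),
    bu   = list(notckd = tn(15, 45),   ckd = tn(15, 150)),
    sc   = list(notckd = sh(0),        ckd = sh(delta)),
    sod  = list(notckd = tn(130, 150), ckd = tn(125, 150)),
    pot  = list(notckd = tn(3.5, 5.5), ckd = tn(3.5, 6.5)),
    hemo = list(notckd = tn(12.5, 17.5), ckd = tn(5, 17.5)),
    pcv  = list(notckd = tn(40, 60),   ckd = tn(20, 50)),
    wc   = list(notckd = tn(4000, 11000), ckd = tn(4000, 12000)),
    rc   = list(notckd = tn(4, 7),     ckd = tn(3, 6))
  )
  rates <- list(
    rbc = c(notckd = 0.02, ckd = 0.30), pc  = c(notckd = 0.02, ckd = 0.35),
    pcc = c(notckd = 0.02, ckd = 0.20), ba  = c(notckd = 0.02, ckd = 0.15),
    htn = c(notckd = 0.05, ckd = 0.60), dm  = c(notckd = 0.05, ckd = 0.55),
    cad = c(notckd = 0.02, ckd = 0.25), appet = c(notckd = 0.98, ckd = 0.60),
    pe  = c(notckd = 0.02, ckd = 0.35), ane = c(notckd = 0.02, ckd = 0.35)
  )
  if (!is.null(numeric_dists)) dists[names(numeric_dists)] <- numeric_dists
  if (!is.null(binary_rates)) rates[names(binary_rates)] <- binary_rates
  for (f in names(dists)) for (cl in c("notckd", "ckd")) {
    d <- dists[[f]][[cl]]
    if (d$dist %in% c("truncnorm", "uniform") && d$low > d$high)
      stop("invalid range for '", f, "': low > high")
  }
  for (f in names(rates)) if (any(rates[[f]] < 0 | rates[[f]] > 1))
    stop("rates for '", f, "' must be in [0,1]")
  structure(list(n_per_class = n_per_class, missing_rate = missing_rate,
                 delta = delta, seed = as.integer(seed),
                 numeric_dists = dists, binary_rates = rates),
            class = "ckd_synthetic_spec")
}

rtruncnorm_vec <- function(n, mean, sd, low, high) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= low & draw <= high
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

draw_numeric <- function(n, d) {
  switch(d$dist,
         truncnorm = rtruncnorm_vec(n, d$mean, d$sd, d$low, d$high),
         uniform = stats::runif(n, d$low, d$high),
         normal = stats::rnorm(n, d$mean, d$sd),
         stop("unknown distribution tag: ", d$dist))
}

#' Generate a synthetic CKD-like dataset
#'
#' Draws `n_per_class` patients per class from the class-conditional
#' distributions in the spec, then masks cells independently at
#' `missing_rate`. The same seed gives a bit-identical dataset.
#'
#' @param spec a [synthetic_spec()].
#' @param schema feature schema.
#' @return a [ckd_dataset()] with exactly balanced classes
#'   (rows 1..n_per_class are notckd, the rest ckd).
#' @export
generate_synthetic <- function(spec = synthetic_spec(), schema = ckd_schema()) {
  if (!inherits(spec, "ckd_synthetic_spec")) stop("spec must be a synthetic_spec()")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  m <- spec$n_per_class
  n <- 2L * m
  d <- length(schema$names)
  X <- matrix(NA_real_, n, d, dimnames = list(NULL, schema$names))
  i0 <- seq_len(m); i1 <- m + seq_len(m)
  for (f in schema$names) {
    if (f %in% names(spec$numeric_dists)) {
      X[i0, f] <- draw_numeric(m, spec$numeric_dists[[f]]$notckd)
      X[i1, f] <- draw_numeric(m, spec$numeric_dists[[f]]$ckd)
    } else {
      r <- spec$binary_rates[[f]]
      X[i0, f] <- stats::rbinom(m, 1L, r[["notckd"]])
      X[i1, f] <- stats::rbinom(m, 1L, r[["ckd"]])
    }
  }
  mask <- matrix(stats::runif(n * d) < spec$missing_rate, n, d)
  y <- c(rep(0L, m), rep(1L, m))
  ckd_dataset(X, mask, y, schema, "synthetic")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic UCI-dialect ARFF stand-in file
#'
#' Produces an ARFF file in the dirty UCI dialect (attribute declarations,
#' `?` for missing, a sprinkling of stray tab characters) with 400 records,
#' 250 ckd / 150 notckd, of which exactly 158 are complete — the record
#' counts of the public file. The values themselves are synthetic draws;
#' this is a structural stand-in for parser and pipeline exercise, not real
#' patient data.
#'
#' @param path output path.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
synthetic_uci_arff <- function(path, seed = 42L) {
  schema <- ckd_schema()
  full <- generate_synthetic(synthetic_spec(n_per_class = 250L, seed = seed))
  # 250 ckd + 150 notckd, interleaved deterministically
  idx <- c(which(full$y == 1L), which(full$y == 0L)[1:150])
  ds <- dataset_rows(full, idx)
  n <- nrow(ds$X); d <- ncol(ds$X)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  complete_rows <- sort(sample.int(n, 158L))
  mask <- matrix(FALSE, n, d)
  for (i in setdiff(seq_len(n), complete_rows)) {
    k <- 1L + stats::rbinom(1L, d - 1L, 0.08)
    mask[i, sample.int(d, k)] <- TRUE
  }
  ds <- ckd_dataset(ifelse(mask, NA_real_, ds$X), mask, ds$y, schema, "synthetic")

  binary <- schema_binary_features(schema)
  lines <- c("@relation Chronic_Kidney_Disease",
             vapply(schema$names, function(f) {
               if (f %in% binary)
                 sprintf("@attribute '%s' {%s}", f,
                         paste(names(schema$categorical_levels[[f]]), collapse = ","))
               else sprintf("@attribute '%s' numeric", f)
             }, character(1)),
             "@attribute 'class' {ckd,notckd}", "@data")
  body <- vapply(seq_len(n), function(i) {
    cells <- vapply(seq_len(d), function(j) {
      f <- schema$names[j]
      if (ds$mask[i, j]) return("?")
      v <- ds$X[i, j]
      if (f %in% binary) {
        codes <- schema$categorical_levels[[f]]
        names(codes)[match(v, codes)]
      } else num_to_str(round(v, 3))
    }, character(1))
    # reproduce the tab pollution seen in the real file on a few rows
    if (i %% 37L == 0L) cells[1] <- paste0("\t", cells[1])
    paste(c(cells, if (ds$y[i] == 1L) "ckd" else "notckd"), collapse = ",")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
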