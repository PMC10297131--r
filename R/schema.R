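#' Feature schema for the 24-feature CKD table
#'
#' Describes the 24 clinical features of the UCI chronic kidney disease
#' table: column order, per-feature kind (numeric, ordinal numeric, or
#' binary categorical), and the string-level to numeric-code mapping used
#' for categorical columns.
#'
#' Coding convention (fixed so runs are reproducible): for binary features
#' the "present/abnormal/yes" level codes to 1 and "notpresent/normal/no"
#' to 0; appetite codes good -> 1, poor -> 0. Specific gravity, albumin and
#' sugar (`sg`, `al`, `su`) are ordinal but numeric-valued in the source
#' file and are treated as ordinal numerics.
#'
#' @return An object of class `ckd_schema`: a list with `names` (24 feature
#'   identifiers in file order), `kinds` (named character vector with values
#'   `"numeric"`, `"categorical-binary"` or `"categorical-ordinal"`), and
#'   `categorical_levels` (named list; for each categorical feature a named
#'   numeric vector mapping level string -> code).
#' @examples
#' sc <- ckd_schema()
#' sc$names
#' sc$categorical_levels$htn
#' @export
ckd_schema <- function() {
  names <- c("age", "bp", "sg", "al", "su", "rbc", "pc", "pcc", "ba",
             "bgr", "bu", "sc", "sod", "pot", "hemo", "pcv", "wc", "rc",
             "htn", "dm", "cad", "appet", "pe", "ane")
  kinds <- c(age = "numeric", bp = "numeric",
             sg = "categorical-ordinal", al = "categorical-ordinal",
             su = "categorical-ordinal",
             rbc = "categorical-binary", pc = "categorical-binary",
             pcc = "categorical-binary", ba = "categorical-binary",
             bgr = "numeric", bu = "numeric", sc = "numeric",
             sod = "numeric", pot = "numeric", hemo = "numeric",
             pcv = "numeric", wc = "numeric", rc = "numeric",
             htn = "categorical-binary", dm = "categorical-binary",
             cad = "categorical-binary", appet = "categorical-binary",
             pe = "categorical-binary", ane = "categorical-binary")
  lv <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }
  categorical_levels <- list(
    # ordinal features keep their numeric-valued levels as identity codes
    sg = lv("1.005" = 1.005, "1.010" = 1.010, "1.015" = 1.015,
            "1.020" = 1.020, "1.025" = 1.025),
    al = lv("0" = 0, "1" = 1, "2" = 2, "3" = 3, "4" = 4, "5" = 5),
    su = lv("0" = 0, "1" = 1, "2" = 2, "3" = 3, "4" = 4, "5" = 5),
    rbc = lv(normal = 0, abnormal = 1),
    pc = lv(normal = 0, abnormal = 1),
    pcc = lv(notpresent = 0, present = 1),
    ba = lv(notpresent = 0, present = 1),
    htn = lv(no = 0, yes = 1),
    dm = lv(no = 0, yes = 1),
    cad = lv(no = 0, yes = 1),
    appet = lv(poor = 0, good = 1),
    pe = lv(no = 0, yes = 1),
    ane = lv(no = 0, yes = 1)
  )
  out <- structure(list(names = names, kinds = kinds,
                        categorical_levels = categorical_levels),
                   class = "ckd_schema")
  validate_schema(out)
  out
}

validate_schema <- function(schema) {
  stopifnot(inherits(schema, "ckd_schema"))
  if (length(schema$names) != 24L || anyDuplicated(schema$names))
    stop("schema must have 24 unique feature names")
  if (!setequal(names(schema$kinds), schema$names))
    stop("schema kinds must cover exactly the feature names")
  for (f in names(schema$categorical_levels)) {
    codes <- schema$categorical_levels[[f]]
    if (length(codes) < 2L) stop("categorical feature '", f, "' needs >= 2 levels")
    if (anyDuplicated(codes)) stop("codes for '", f, "' must be distinct")
  }
  invisible(schema)
}

#' Feature kind helpers
#'
#' @param schema a `ckd_schema`
#' @return character vector of feature names of the given kind.
#' @keywords internal
schema_numeric_features <- function(schema) {
  # ordinal features behave as numerics in every arithmetic step
  schema$names[schema$kinds[schema$names] != "categorical-binary"]
}

schema_binary_features <- function(schema) {
  schema$names[schema$kinds[schema$names] == "categorical-binary"]
}
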