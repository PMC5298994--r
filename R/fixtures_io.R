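# Packaged fixtures: the published 16-dye uptake panel and the 9x11 table of
# selected molecular descriptors, plus PaDEL-style CSV readers/writers.

.fixture_md5 <- c(
  dye_panel.csv        = "8833e9156ed567e903abe2fa18c9003e",
  descriptor_table.csv = "6aea85848d613e510216a8eac7f78b09"
)

# Table 2 uses slightly different molecule spellings than Table 1; the join
# from descriptor rows to panel classes goes through this explicit alias map
# (exact string matching everywhere else).
.panel_aliases <- c(
  "Procion orange MX2R"  = "Procion Orange MX2R",
  "Ethidium homodimer-2" = "Ethidium homodimer"
)

.fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "poreperm")
  if (!nzchar(path))
    stop("packaged fixture '", file, "' not found", call. = FALSE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[file]])))
    stop("integrity error: checksum mismatch for packaged fixture '", file,
         "' (expected ", .fixture_md5[[file]], ", got ", md5, ")",
         call. = FALSE)
  path
}

#' Load the packaged dye uptake panel
#'
#' The 16 fluorescent tracers assayed for uptake through Cx39 hemichannels,
#' with molecular weight (Da), net charge (elementary charges), uptake class
#' (`permeant`/`non_permeant`) and whether uptake was inhibited by a
#' hemichannel blocker (`yes`, or `not_applicable` for non-permeant dyes).
#' The file's MD5 checksum is verified on every load.
#'
#' @return A data frame of class `dye_panel` with 16 rows and columns
#'   `name`, `molecular_weight`, `net_charge`, `uptake_class`,
#'   `blocker_inhibited`.
#' @examples
#' panel <- load_dye_panel()
#' table(panel$uptake_class)
#' @export
load_dye_panel <- function() {
  path <- .fixture_path("dye_panel.csv")
  panel <- utils::read.csv(path, check.names = FALSE,
                           colClasses = c("character", "numeric", "integer",
                                          "character", "character"))
  stopifnot(
    nrow(panel) == 16L,
    !anyDuplicated(panel$name),
    all(panel$molecular_weight > 0),
    all(panel$net_charge >= -4L & panel$net_charge <= 4L),
    all(panel$uptake_class %in% c("permeant", "non_permeant")),
    all(panel$blocker_inhibited[panel$uptake_class == "non_permeant"] ==
          "not_applicable")
  )
  class(panel) <- c("dye_panel", "data.frame")
  panel
}

#' Load the packaged molecular descriptor table
#'
#' The published table of the 11 selected molecular descriptors (TDB6e,
#' ATSC5s, GATS5s, TDB8i, TDB10i, TDB6p, TDB6r, TDB6v, TDB5u, RotBtFrac,
#' VP-6) for the 9 molecules with printed values, with permeability class
#' labels joined from [load_dye_panel()] (6 permeant, 3 non-permeant).
#'
#' @return A labelled [descriptor_matrix()] of dimension 9 x 11 with no
#'   missing values.
#' @examples
#' dm <- load_descriptor_table()
#' dm$values["Ethidium bromide", "TDB6e"]
#' @export
load_descriptor_table <- function() {
  path <- .fixture_path("descriptor_table.csv")
  dm <- read_descriptor_csv(path, name_column = "Name")
  panel <- load_dye_panel()
  cls <- stats::setNames(panel$uptake_class, panel$name)
  keys <- molecule_names(dm)
  aliased <- ifelse(keys %in% names(.panel_aliases),
                    .panel_aliases[keys], keys)
  labels <- unname(cls[aliased])
  stopifnot(!anyNA(labels), dim(dm)[1] == 9L, dim(dm)[2] == 11L,
            !anyNA(dm$values))
  descriptor_matrix(dm$values, labels = labels)
}

#' Read a PaDEL-style descriptor CSV
#'
#' Expects one molecule-name column plus numeric descriptor columns, as
#' written by molecular-descriptor software. Cells equal to one of
#' `missing_tokens` (or otherwise non-numeric) become missing values;
#' column order is preserved.
#'
#' @param path path to a CSV file (RFC-4180 quoting).
#' @param name_column name of the molecule-name column (default `"Name"`).
#' @param missing_tokens character vector of cell values treated as missing.
#'   The default matches common descriptor-software output.
#' @return A [descriptor_matrix()] without labels.
#' @export
read_descriptor_csv <- function(path, name_column = "Name",
                                missing_tokens = c("", "NA", "NaN",
                                                   "Infinity", "-Infinity")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!name_column %in% names(raw))
    stop("format error: name column '", name_column, "' not present",
         call. = FALSE)
  mols <- raw[[name_column]]
  if (anyDuplicated(mols))
    stop("format error: duplicate molecule names", call. = FALSE)
  desc <- raw[setdiff(names(raw), name_column)]
  if (ncol(desc) == 0L)
    stop("format error: zero descriptor columns", call. = FALSE)
  if (anyDuplicated(names(desc)))
    stop("format error: duplicate descriptor names", call. = FALSE)
  vals <- vapply(desc, function(col) {
    col[col %in% missing_tokens] <- NA_character_
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(mols, names(desc)))
  descriptor_matrix(vals)
}

#' Write a descriptor matrix to CSV
#'
#' Values are written with 15 significant digits so that
#' [read_descriptor_csv()] recovers the matrix exactly. Labels are not
#' written (they live in the dye panel, not the descriptor file).
#'
#' @param matrix a [descriptor_matrix()].
#' @param path output path.
#' @param name_column header for the molecule-name column.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(matrix, path, name_column = "Name") {
  if (!inherits(matrix, "descriptor_matrix"))
    stop("`matrix` must be a descriptor_matrix", call. = FALSE)
  if (nrow(matrix$values) == 0L)
    stop("format error: empty molecule list", call. = FALSE)
  chr <- apply(matrix$values, c(1, 2), function(v)
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE))
  out <- data.frame(molecule_names(matrix), chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c(name_column, descriptor_names(matrix))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write to '", path, "'", call. = FALSE)
  invisible(path)
}
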