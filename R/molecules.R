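# Molecule tables, file I/O (.smi / .csv / .sdf) and physicochemical
# properties including the quantitative estimate of drug-likeness (QED).

#' Molecule record table
#'
#' A plain data.frame with columns `molecule_id`, `smiles`, `source` used as
#' the molecule currency throughout the package.
#'
#' @param smiles character vector of SMILES.
#' @param molecule_id character vector of unique ids (defaults to names of
#'   `smiles` or `mol<i>`).
#' @param source library name.
#' @return data.frame of class `c("fp_molecules", "data.frame")`.
#' @export
molecule_records <- function(smiles, molecule_id = NULL, source = "user") {
  molecule_id <- molecule_id %||% names(smiles) %||%
    paste0("mol", seq_along(smiles))
  if (anyDuplicated(molecule_id)) {
    stop("molecule_id values must be unique within a library")
  }
  structure(
    data.frame(molecule_id = as.character(molecule_id),
               smiles = as.character(smiles),
               source = source, stringsAsFactors = FALSE),
    class = c("fp_molecules", "data.frame")
  )
}

#' Read a molecule library
#'
#' Supported formats: `.smi` ("SMILES<tab>id", one per line), `.csv`
#' (columns `smiles` and `id` or `molecule_id`), `.sdf` (converted through
#' Open Babel).
#'
#' @param path input file.
#' @param format override the extension-based format guess
#'   (`"smi"`, `"csv"`, `"sdf"`).
#' @return a [molecule_records()] table; `source` is the file name.
#' @export
read_molecules <- function(path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  src <- basename(path)
  if (format == "smi") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    smiles <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_, "")
    if (anyNA(ids)) ids <- ifelse(is.na(ids), paste0("mol", seq_along(ids)), ids)
    molecule_records(smiles, ids, source = src)
  } else if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    idcol <- intersect(c("molecule_id", "id"), names(df))[1L]
    if (is.na(idcol) || !"smiles" %in% names(df)) {
      stop("CSV molecule file needs columns 'smiles' and 'id'/'molecule_id'")
    }
    molecule_records(df$smiles, df[[idcol]], source = src)
  } else if (format == "sdf") {
    tmp <- tempfile(fileext = ".smi")
    on.exit(unlink(tmp))
    ChemmineOB::convertFormatFile("SDF", "SMI", path, tmp)
    rec <- read_molecules(tmp, format = "smi")
    rec$source <- src
    rec
  } else {
    stop("unsupported molecule file format: ", format)
  }
}

# ---- properties --------------------------------------------------------------

.qed_env <- new.env(parent = emptyenv())

qed_tables <- function() {
  if (is.null(.qed_env$params)) {
    ext <- function(f) system.file("extdata", f, package = "fpgan")
    .qed_env$params <- utils::read.csv(ext("qed_params.csv"),
                                       stringsAsFactors = FALSE)
    read_patterns <- function(f) {
      p <- readLines(ext(f))
      p[nzchar(p) & !startsWith(p, "#")]
    }
    .qed_env$acceptors <- read_patterns("qed_acceptors.smarts")
    alerts <- read_patterns("qed_alerts.smarts")
    # keep only patterns Open Babel's SMARTS engine accepts (the published
    # list contains two disconnected-component patterns it cannot parse)
    probe <- ob_parse(c(probe = "CCO"))
    ok <- vapply(alerts, function(p) {
      !inherits(tryCatch(ChemmineOB::smartsSearch_OB(probe, p),
                         error = identity), "error")
    }, TRUE)
    .qed_env$alerts <- alerts[ok]
    .qed_env$n_alerts_dropped <- sum(!ok)
  }
  .qed_env
}

# asymmetric double sigmoid desirability, scaled by its maximum
qed_ads <- function(x, p) {
  v <- p$a + p$b / (1 + exp(-(x - p$c + p$d / 2) / p$e)) *
    (1 - 1 / (1 + exp(-(x - p$c - p$d / 2) / p$f)))
  pmax(v / p$dmax, 1e-6)
}

smarts_counts <- function(mols, patterns) {
  out <- matrix(0L, length(mols), length(patterns))
  for (j in seq_along(patterns)) {
    out[, j] <- ChemmineOB::smartsSearch_OB(mols, patterns[j],
                                            uniqueMatches = TRUE)
  }
  out
}

#' Molecular properties and drug-likeness profile
#'
#' Computes, per molecule: molecular weight (g/mol, standard atomic masses),
#' Wildman-Crippen logP, Ertl topological polar surface area (TPSA, A^2),
#' hydrogen-bond donor/acceptor counts, rotatable-bond count, aromatic ring
#' count, structural-alert count, the quantitative estimate of drug-likeness
#' (QED, weighted geometric mean of eight desirability functions), and a
#' Lipinski rule-of-five flag (MW <= 500, logP <= 5, HBD <= 5, HBA <= 10).
#'
#' MW, logP and TPSA come from Open Babel's descriptor implementations. HBA
#' uses the QED publication's acceptor SMARTS; HBD counts N/O atoms bearing
#' hydrogen; rotatable bonds use the standard non-terminal, non-ring
#' single-bond SMARTS; aromatic rings are counted as 5-7-membered aromatic
#' ring SMARTS matches. QED therefore closely tracks, but is not bit-identical
#' to, implementations built on other toolkits.
#'
#' @param x character vector of SMILES (optionally named) or a molecule
#'   table with columns `molecule_id`, `smiles`.
#' @return data.frame with one row per molecule: `molecule_id`, `MW`, `logP`,
#'   `TPSA`, `HBD`, `HBA`, `ROTB`, `AROM`, `ALERTS`, `QED`, `lipinski_pass`.
#' @examples
#' \donttest{
#' druglike_profile(c(aspirin = "CC(=O)Oc1ccccc1C(=O)O"))
#' }
#' @export
druglike_profile <- function(x) {
  inp <- as_molecule_input(x)
  mols <- ob_parse(inp$smiles, inp$ids)
  pr <- ChemmineOB::prop_OB(mols)
  q <- qed_tables()
  hba <- rowSums(smarts_counts(mols, q$acceptors))
  hbd <- as.numeric(ChemmineOB::smartsSearch_OB(mols, "[#7,#8;!H0]"))
  rotb <- as.numeric(ChemmineOB::smartsSearch_OB(
    mols, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"))
  arom <- rowSums(smarts_counts(
    mols, c("a1aaaa1", "a1aaaaa1", "a1aaaaaa1")))
  alerts <- rowSums(smarts_counts(mols, q$alerts) >= 1L)

  vals <- list(MW = pr$MW, ALOGP = pr$logP, HBA = hba, HBD = hbd,
               PSA = pr$TPSA, ROTB = rotb, AROM = arom, ALERTS = alerts)
  par <- q$params
  logd <- 0
  wsum <- sum(par$weight)
  for (i in seq_len(nrow(par))) {
    p <- as.list(par[i, ])
    logd <- logd + p$weight * log(qed_ads(vals[[p$property]], p))
  }
  qed <- exp(logd / wsum)

  data.frame(
    molecule_id = inp$ids,
    MW = pr$MW, logP = pr$logP, TPSA = pr$TPSA,
    HBD = hbd, HBA = hba, ROTB = rotb, AROM = arom, ALERTS = alerts,
    QED = qed,
    lipinski_pass = pr$MW <= 500 & pr$logP <= 5 & hbd <= 5 & hba <= 10,
    stringsAsFactors = FALSE
  )
}

#' Molecular weight / logP property table
#'
#' Lightweight helper returning the two properties used for decoy matching.
#'
#' @inheritParams druglike_profile
#' @return data.frame with columns `molecule_id`, `MW`, `logP`.
#' @export
property_table <- function(x) {
  inp <- as_molecule_input(x)
  mols <- ob_parse(inp$smiles, inp$ids)
  pr <- ChemmineOB::prop_OB(mols)
  data.frame(molecule_id = inp$ids, MW = pr$MW, logP = pr$logP,
             stringsAsFactors = FALSE)
}
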