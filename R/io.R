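## Serialisation of mixtures and provenance to plain lists (for the JSON
## metadata header of titration CSV files).

serialize_mixture <- function(mix) {
  prot <- mix$protein
  protein <- if (inherits(prot, "intact_params")) {
    list(kind = "intact",
         N = unclass(prot$N)[c("L", "K_R", "K_T")],
         C = unclass(prot$C)[c("L", "K_R", "K_T")])
  } else {
    c(list(kind = "lobe"), unclass(prot)[c("L", "K_R", "K_T")])
  }
  targets <- lapply(mix$targets, function(t) {
    if (inherits(t, "intact_target_spec"))
      c(list(kind = "intact_target"),
        unclass(t)[c("name", "K_RR", "K_RT", "K_TR", "K_TT")])
    else
      c(list(kind = "target"),
        unclass(t)[c("name", "K_Rt", "K_Tt", "stoichiometry", "bounds")])
  })
  list(protein = protein, protein_total = mix$protein_total,
       targets = targets, target_totals = as.numeric(mix$target_totals),
       calcium_mode = mix$calcium_mode, binding = mix$binding)
}

deserialize_mixture <- function(x) {
  prot <- if (identical(x$protein$kind, "intact")) {
    intact_params(N = do.call(lobe_params, x$protein$N),
                  C = do.call(lobe_params, x$protein$C))
  } else {
    lobe_params(x$protein$L, x$protein$K_R, x$protein$K_T)
  }
  targets <- lapply(x$targets, function(t) {
    if (identical(t$kind, "intact_target"))
      intact_target_spec(t$name, t$K_RR, t$K_RT, t$K_TR, t$K_TT)
    else
      target_spec(t$name, t$K_Rt, t$K_Tt, stoichiometry = t$stoichiometry,
                  bounds = isTRUE(t$bounds))
  })
  cam_mixture(prot, x$protein_total, targets = targets,
              target_totals = as.numeric(x$target_totals),
              calcium_mode = x$calcium_mode, binding = x$binding)
}

#' Write a titration dataset to CSV
#'
#' Comma-separated values with a `#`-prefixed metadata header carrying
#' the composition (as a JSON-encoded mixture) and the generation
#' provenance (seed, noise model), so a dataset round-trips through disk
#' with its full context. Units are molar throughout; decimal point `.`.
#'
#' @param data A `cam_titration` tibble (or any data frame with
#'   `ca_free_molar` and `saturation` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# hemicam titration dataset (concentrations in molar)", con)
  mix <- attr(data, "mixture")
  if (!is.null(mix))
    writeLines(paste0("# mixture: ",
                      jsonlite::toJSON(serialize_mixture(mix),
                                       auto_unbox = TRUE, digits = NA)), con)
  prov <- attr(data, "provenance")
  if (!is.null(prov))
    writeLines(paste0("# provenance: ",
                      jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA)),
               con)
  utils::write.csv(as.data.frame(data), con, row.names = FALSE)
  invisible(path)
}

#' Read a titration dataset from CSV
#'
#' Counterpart of [write_titration_csv()]: parses the `#` metadata header
#' (mixture composition and provenance, when present) and the data rows.
#' Rows are sorted by ascending calcium; missing required columns or
#' non-numeric values are reported with their location.
#'
#' @param path CSV file path with columns `ca_free_molar`, `saturation`.
#' @return A `cam_titration` tibble with `mixture` and `provenance`
#'   attributes when the header carries them.
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  df <- utils::read.csv(text = lines[body], stringsAsFactors = FALSE)
  need <- c("ca_free_molar", "saturation")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column %s at data row %d", col,
                   bad[1]))
    if (anyNA(vals)) stop("missing value in column ", col)
    df[[col]] <- vals
  }
  if (!"weight" %in% names(df)) df$weight <- 1
  out <- tibble::as_tibble(df[order(df$ca_free_molar), ])
  get_meta <- function(key) {
    line <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(line) == 0) return(NULL)
    jsonlite::fromJSON(sub(paste0("^# ", key, ": "), "", line[1]),
                       simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  mix_meta <- get_meta("mixture")
  if (!is.null(mix_meta)) attr(out, "mixture") <- deserialize_mixture(mix_meta)
  prov <- get_meta("provenance")
  if (!is.null(prov)) attr(out, "provenance") <- prov
  class(out) <- c("cam_titration", class(out))
  out
}

#' Write a saturation curve to CSV
#'
#' Columns `ca_free_molar`, `saturation`, and `free_<target>_molar` for
#' each target, with a metadata header describing the mixture.
#'
#' @param curve A `cam_curve` tibble from [titration_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  write_titration_csv(curve, path)
}
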