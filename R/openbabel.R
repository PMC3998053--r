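# Batched bridge to the OpenBabel command-line converter.
#
# All chemistry that is not graph editing -- SMILES parsing, canonical
# SMILES, fingerprint generation -- is delegated to obabel. Calls are
# batched: one subprocess handles an arbitrary number of molecules, so the
# per-molecule cost inside the exploration loop stays in the microsecond
# range.

ob_executable <- function() {
  path <- Sys.which("obabel")
  if (!nzchar(path)) {
    stop("the 'obabel' executable (OpenBabel >= 3) was not found on PATH; ",
         "it is required for SMILES parsing and fingerprints", call. = FALSE)
  }
  path
}

# Run obabel on `input` (a single string, possibly multi-record) and return
# stdout as a character vector of lines. `args` follow the input/output
# format flags.
ob_run <- function(input, in_format, out_format, args = character()) {
  exe <- ob_executable()
  fin <- tempfile(fileext = paste0(".", in_format))
  fout <- tempfile(fileext = ".out")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input, fin)
  status <- suppressWarnings(system2(
    exe,
    c(fin, paste0("-i", in_format), paste0("-o", out_format),
      "-O", fout, args),
    stdout = FALSE, stderr = FALSE
  ))
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("obabel conversion ", in_format, " -> ", out_format, " failed",
         call. = FALSE)
  }
  readLines(fout, warn = FALSE)
}

# Canonical SMILES for a batch of inputs. `input` is either a character
# vector of SMILES or a single multi-record SDF string; ids must be unique
# non-empty tokens without whitespace. Returns a named character vector
# (may be shorter than the input: molecules obabel could not parse are
# simply absent, which callers use to detect parse failures).
ob_canonical <- function(input, ids, from = c("smi", "sdf")) {
  from <- match.arg(from)
  if (from == "smi") {
    stopifnot(length(input) == length(ids))
    payload <- paste(input, ids)
  } else {
    payload <- input
  }
  out <- ob_run(payload, from, "can")
  out <- out[nzchar(out)]
  if (length(out) == 0) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(out, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, "", 1L)
  nm <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "", "")
  stats::setNames(smi, nm)
}

# Batch fingerprints in FPS (hex) format. Returns a list keyed by id of raw
# vectors (packed bits, little-endian within the hex convention obabel
# uses -- consistent across all calls, which is all similarity needs).
ob_fingerprints <- function(input, ids, ob_name, nbits = NULL,
                            from = c("smi", "sdf")) {
  from <- match.arg(from)
  if (from == "smi") {
    stopifnot(length(input) == length(ids))
    payload <- paste(input, ids)
  } else {
    payload <- input
  }
  args <- c(paste0("-xf", ob_name))
  if (!is.null(nbits)) args <- c(args, paste0("-xN", nbits))
  out <- ob_run(payload, from, "fps", args)
  out <- out[nzchar(out) & !startsWith(out, "#")]
  parts <- strsplit(out, "\t", fixed = TRUE)
  hex <- vapply(parts, `[[`, "", 1L)
  nm <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "", "")
  fps <- lapply(hex, hex_to_raw)
  stats::setNames(fps, nm)
}

hex_to_raw <- function(hex) {
  n <- nchar(hex)
  as.raw(strtoi(substring(hex, seq(1L, n, 2L), seq(2L, n, 2L)), 16L))
}
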