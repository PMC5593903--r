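#' Read a residue-signature table
#'
#' Signatures are data, not code: a TSV with columns `signature` (name),
#' `ref_position` (reference numbering), `residues` (string of allowed
#' one-letter codes, e.g. `CG` for Cys-or-Gly) and `role`
#' (`required` or `forbidden`). Users can encode any family this way.
#'
#' @param path Path to a signature TSV.
#' @return A `signature_set` tibble.
#' @export
read_signatures <- function(path) {
  sig <- readr::read_tsv(path, col_types = readr::cols(
    signature = readr::col_character(),
    ref_position = readr::col_integer(),
    residues = readr::col_character(),
    role = readr::col_character()
  ))
  validate_signatures(sig)
}

validate_signatures <- function(sig) {
  needed <- c("signature", "ref_position", "residues", "role")
  if (!all(needed %in% names(sig))) {
    abort(sprintf(
      "A signature table needs columns %s.", paste(needed, collapse = ", ")
    ))
  }
  if (any(!nzchar(sig$residues))) {
    abort("Every signature position needs a non-empty allowed-residue list.")
  }
  if (!all(sig$role %in% c("required", "forbidden"))) {
    abort("Signature `role` must be 'required' or 'forbidden'.")
  }
  sig <- as_tibble(sig)
  class(sig) <- unique(c("signature_set", class(sig)))
  sig
}

#' Write a signature table
#' @param sig A `signature_set` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sig, path) {
  readr::write_tsv(sig, path)
  invisible(path)
}

#' Built-in family signatures
#'
#' Shipped signature tables for the two arsenic-metabolism families:
#'
#' * `"arsC"` (arsenate reductase, ArsC/PF03960-style domain; positions in
#'   E. coli ArsC numbering): the highly conserved triad Arg94/Pro95 and
#'   Cys-or-Gly106; coevolved sets `set1` (Arg60, Arg107, Pro108, required
#'   for arsenate reduction), `set2` (His8, Asn9, Ser15), `set3`
#'   (Cys12 with Leu/Ile22) and `set4` (Lys93 with Asn60, characteristic of
#'   the paralogs YffB/YusI). Two single-position discriminators are
#'   shipped separately: `arsC_like` (Cys106) and `spx_like` (Gly106) — the
#'   Spx regulatory paralog carries a conserved Gly at 106 while reductases
#'   favour Cys. Note positions 60 appears in both set1 (Arg) and set4
#'   (Asn): the two sets describe mutually exclusive subfamily states of
#'   the same column.
#' * `"aioA"` (arsenite oxidase large subunit, molybdopterin domain;
#'   positions in the molybdopterin reference numbering): the thirteen
#'   highly conserved residues (Arg112, Pro116, Trp167, Ala170, Gly258,
#'   Pro287, Asp307, Ala518, Gly557, Gly563, Leu778, Pro779, Glu785) and
#'   six coevolved sets.
#'
#' @param family `"arsC"` or `"aioA"`.
#' @return A `signature_set` tibble.
#' @export
#' @examples
#' builtin_signatures("arsC")
builtin_signatures <- function(family = c("arsC", "aioA")) {
  family <- match.arg(family)
  path <- system.file(
    "extdata", paste0("signatures_", family, ".tsv"),
    package = "famsig", mustWork = TRUE
  )
  read_signatures(path)
}

#' Score one sequence against one signature
#'
#' @param states Tibble of residue states for one sequence: columns
#'   `ref_pos`, `residue` (e.g. one id's rows from [alignment_states()] or
#'   [map_peptide_to_reference()]).
#' @param sig One signature: rows of a `signature_set` sharing a name.
#' @param span Optional length-2 vector of the reference span the sequence
#'   covers; defaults to the range of `states$ref_pos`. A signature is
#'   `"not_assessable"` when any required position falls outside the span
#'   (e.g. position 12 against an amplicon covering 27-116); otherwise it is
#'   `"present"` iff every required position carries an allowed residue and
#'   no forbidden position does.
#' @return `"present"`, `"absent"` or `"not_assessable"`.
#' @export
score_sequence <- function(states, sig, span = NULL) {
  if (nrow(states) == 0) {
    return("not_assessable")
  }
  span <- span %||% range(states$ref_pos)
  req <- sig[sig$role == "required", , drop = FALSE]
  forb <- sig[sig$role == "forbidden", , drop = FALSE]
  if (nrow(req) > 0 &&
      any(req$ref_position < span[[1]] | req$ref_position > span[[2]])) {
    return("not_assessable")
  }
  state_at <- function(pos) states$residue[match(pos, states$ref_pos)]
  if (nrow(req) > 0) {
    got <- state_at(req$ref_position)
    ok <- !is.na(got) & stringr::str_detect(req$residues, stringr::fixed(got))
    if (!all(ok)) {
      return("absent")
    }
  }
  if (nrow(forb) > 0) {
    inspan <- forb$ref_position >= span[[1]] & forb$ref_position <= span[[2]]
    got <- state_at(forb$ref_position[inspan])
    hit <- !is.na(got) &
      stringr::str_detect(forb$residues[inspan], stringr::fixed(got))
    if (any(hit)) {
      return("absent")
    }
  }
  "present"
}

#' Classify sequences against residue signatures
#'
#' Applies every signature to every sequence, reporting per-sequence status
#' calls and, per signature, the fraction present among assessable
#' sequences. Classification is deterministic and order-independent.
#'
#' @param states Long tibble of residue states: columns `id`, `ref_pos`,
#'   `residue` (from [alignment_states()] or [map_amplicons()]).
#' @param signatures A `signature_set` tibble (e.g.
#'   [builtin_signatures()]), possibly holding many named signatures.
#' @param spans Optional tibble (`id`, `ref_start`, `ref_end`) overriding
#'   each sequence's assessable span; defaults to the range of its states.
#' @return A `signature_classification` object: list with `calls`
#'   (tibble `id`, `signature`, `status`) and `aggregate` (tibble
#'   `signature`, `n_present`, `n_absent`, `n_not_assessable`,
#'   `fraction_present`).
#' @export
classify <- function(states, signatures, spans = NULL) {
  if (!is.data.frame(states) ||
      !all(c("id", "ref_pos", "residue") %in% names(states))) {
    abort("`states` must have columns `id`, `ref_pos`, `residue`.")
  }
  if (nrow(states) == 0) abort("No sequences to classify.")
  signatures <- validate_signatures(signatures)
  if (nrow(signatures) == 0) abort("Empty signature set.")
  ids <- sort(unique(states$id))
  sig_names <- unique(signatures$signature)
  by_id <- split(states, states$id)
  span_of <- function(id) {
    if (!is.null(spans)) {
      row <- spans[spans$id == id, , drop = FALSE]
      if (nrow(row) == 1) {
        return(c(row$ref_start[[1]], row$ref_end[[1]]))
      }
    }
    NULL
  }
  calls <- tidyr::expand_grid(id = ids, signature = sig_names)
  calls$status <- purrr::map2_chr(calls$id, calls$signature, function(i, s) {
    score_sequence(
      by_id[[i]],
      signatures[signatures$signature == s, , drop = FALSE],
      span = span_of(i)
    )
  })
  aggregate <- calls |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      n_present = sum(.data$status == "present"),
      n_absent = sum(.data$status == "absent"),
      n_not_assessable = sum(.data$status == "not_assessable"),
      fraction_present = if (sum(.data$status != "not_assessable") == 0) {
        NA_real_
      } else {
        sum(.data$status == "present") / sum(.data$status != "not_assessable")
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$signature, sig_names))
  out <- list(calls = calls, aggregate = aggregate)
  class(out) <- "signature_classification"
  out
}

#' @method tidy signature_classification
#' @export
tidy.signature_classification <- function(x, ...) x$calls

#' @method glance signature_classification
#' @export
glance.signature_classification <- function(x, ...) x$aggregate

#' @export
print.signature_classification <- function(x, ...) {
  cat(sprintf(
    "Signature classification: %d sequences x %d signatures\n",
    dplyr::n_distinct(x$calls$id), nrow(x$aggregate)
  ))
  print(x$aggregate)
  invisible(x)
}
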