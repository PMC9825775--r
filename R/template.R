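#' Substitution context for command and filename templates
#'
#' @param scbam_path Path of the generated scBAM, substituted for `{}`.
#'   May be `NULL` when rendering filename templates, in which case `{}`
#'   is left untouched.
#' @param barcode Cell barcode, substituted for `{BARCODE}`.
#' @param bambase Input BAM filename without its path or `.bam` extension,
#'   substituted for `{BAMBASE}` (see [bambase_of()]).
#' @return A list of class `template_context`.
#' @export
template_context <- function(scbam_path = NULL, barcode = NULL, bambase = NULL) {
  if (!is.null(bambase) &&
      (grepl("/", bambase, fixed = TRUE) || grepl("\\.bam$", bambase)))
    stop("bambase must not contain a path separator or end in '.bam'",
         call. = FALSE)
  structure(list(scbam_path = scbam_path, barcode = barcode,
                 bambase = bambase),
            class = "template_context")
}

#' Input-BAM base name for template substitution
#'
#' The final path component with a trailing `.bam` (case-sensitive)
#' removed: `"/data/run7/sample1.bam"` becomes `"sample1"`, and only the
#' final extension is stripped (`"pooled.sorted.bam"` -> `"pooled.sorted"`).
#'
#' @param input_bam_path Path to the input BAM.
#' @return The base name string.
#' @export
bambase_of <- function(input_bam_path) {
  stopifnot(is.character(input_bam_path), nzchar(input_bam_path))
  sub("\\.bam$", "", basename(input_bam_path))
}

#' Render a template with xargs-style substitution
#'
#' Every occurrence of `{}` is replaced by the scBAM path, `{BARCODE}` by
#' the barcode, and `{BAMBASE}` by the input base name -- plain text
#' replacement, left to right, case-sensitive; no other brace sequences are
#' touched and there is no escaping mechanism (so a literal `{}` cannot
#' appear in a template).
#'
#' @param template Template text.
#' @param ctx A [template_context()].
#' @return The rendered text.
#' @examples
#' ctx <- template_context("t/ACGT.bam", barcode = "ACGT", bambase = "sample1")
#' render_template("gatk HaplotypeCaller -I {} -O {BARCODE}.vcf", ctx)
#' @export
render_template <- function(template, ctx) {
  stopifnot(is.character(template), length(template) == 1L, nzchar(template),
            inherits(ctx, "template_context"))
  out <- template
  if (!is.null(ctx$scbam_path))
    out <- gsub("{}", ctx$scbam_path, out, fixed = TRUE)
  if (!is.null(ctx$barcode))
    out <- gsub("{BARCODE}", ctx$barcode, out, fixed = TRUE)
  if (!is.null(ctx$bambase))
    out <- gsub("{BAMBASE}", ctx$bambase, out, fixed = TRUE)
  out
}

#' Render a command template, appending the scBAM path when token-free
#'
#' Follows the find/xargs convention: if the template contains none of the
#' replacement tokens `{}`, `{BARCODE}`, `{BAMBASE}`, the scBAM filename is
#' appended at the end of the command; the presence of any token suppresses
#' appending.
#'
#' @inheritParams render_template
#' @return The shell command to execute.
#' @examples
#' ctx <- template_context("t/ACGT.bam", barcode = "ACGT", bambase = "s1")
#' render_command("samtools flagstat", ctx)   # path appended
#' render_command("script.sh {BARCODE}", ctx) # no appending
#' @export
render_command <- function(template, ctx) {
  stopifnot(is.character(template), length(template) == 1L, nzchar(template))
  has_token <- any(vapply(c("{}", "{BARCODE}", "{BAMBASE}"),
                          function(tk) grepl(tk, template, fixed = TRUE),
                          logical(1)))
  if (!has_token) paste(template, ctx$scbam_path) else
    render_template(template, ctx)
}
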