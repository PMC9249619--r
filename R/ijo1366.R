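#' Locate a local copy of the iJO1366 genome-scale model
#'
#' The headline analyses run against the BiGG iJO1366 reconstruction of
#' *E. coli* K-12 MG1655. This helper finds a local SBML copy without any
#' network access, trying in order: an explicit `path`, the
#' `fluxforce.ijo1366` option, the `FLUXFORCE_IJO1366` environment
#' variable, and finally the copy bundled with the cobra Python toolbox
#' (`cobra/data/iJO1366.xml.gz`) when a python interpreter with cobra is
#' on the PATH.
#'
#' @param path optional explicit file path.
#' @return a file path, or `NULL` when no copy can be found.
#' @export
find_ijo1366 <- function(path = NULL) {
  cands <- c(path,
             getOption("fluxforce.ijo1366", NULL),
             Sys.getenv("FLUXFORCE_IJO1366", unset = NA))
  for (p in cands) {
    if (!is.null(p) && !is.na(p) && nzchar(p)) {
      if (file.exists(p)) return(p)
    }
  }
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  p <- tryCatch(
    system2(py, c("-c", shQuote(paste0(
      "import cobra, os; ",
      "print(os.path.join(os.path.dirname(cobra.__file__), 'data', 'iJO1366.xml.gz'))"))),
      stdout = TRUE, stderr = FALSE),
    error = function(e) character(), warning = function(w) character())
  if (length(p) == 1L && file.exists(p)) return(p)
  NULL
}
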