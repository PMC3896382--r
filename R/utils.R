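# Atomic text output: write to a temp file in the target directory, then
# rename over the destination, so readers never observe a half-written file.

write_lines_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  readr::write_lines(lines, tmp)
  if (!file.rename(tmp, path)) abort(paste0("could not write ", path))
  invisible(path)
}

write_tsv_atomic <- function(x, path, col_names = TRUE) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  readr::write_tsv(x, tmp, col_names = col_names, progress = FALSE)
  if (!file.rename(tmp, path)) abort(paste0("could not write ", path))
  invisible(path)
}
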