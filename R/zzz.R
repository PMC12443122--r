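# Minimal containers sometimes ship no /usr/share/zoneinfo and leave TZDIR
# unset; named-zone conversions then silently degrade to UTC, which would
# corrupt every DST-aware schedule. Detect that and point TZDIR at a zoneinfo
# tree shipped alongside the R installation.

tz_database_broken <- function() {
  t <- suppressWarnings(as.POSIXct("2020-07-01 12:00:00", tz = "America/New_York"))
  !identical(suppressWarnings(format(t, "%z")), "-0400")
}

.onLoad <- function(libname, pkgname) {
  if (!nzchar(Sys.getenv("TZDIR")) && tz_database_broken()) {
    cand <- c(file.path(R.home(), "..", "..", "share", "zoneinfo"),
              "/usr/share/zoneinfo", "/usr/lib/zoneinfo")
    cand <- cand[file.exists(file.path(cand, "UTC"))]
    if (length(cand)) Sys.setenv(TZDIR = normalizePath(cand[1]))
  }
}
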