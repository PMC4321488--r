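# Hand-built CrystFEL-stream fixture: three chunks, two carrying crystals
# (the two crystal-form median cells, in nm), one without.
crystfel_fixture <- function() {
  c("CrystFEL stream format 2.3",
    "----- Begin chunk -----",
    "Image filename: run0001.cxi",
    "Event: //17",
    "--- Begin crystal",
    "Cell parameters 6.90000 16.90000 28.80000 nm, 90.00000 90.00000 90.00000 deg",
    "astar = +0.1449275 +0.0000000 +0.0000000 nm^-1",
    "bstar = +0.0000000 +0.0591716 +0.0000000 nm^-1",
    "cstar = +0.0000000 +0.0000000 +0.0347222 nm^-1",
    "Reflections measured after indexing",
    "   h    k    l          I   sigma(I)       peak background  fs/px  ss/px panel",
    "   1    0    0     123.45      12.30      130.00      10.00  100.0  200.0 q0",
    "   0    2    1      88.00       9.10       90.00       8.00  110.0  210.0 q0",
    "End of reflections",
    "--- End crystal",
    "----- End chunk -----",
    "----- Begin chunk -----",
    "Image filename: run0002.cxi",
    "----- End chunk -----",
    "----- Begin chunk -----",
    "Image filename: run0003.cxi",
    "--- Begin crystal",
    "Cell parameters 6.90000 14.60000 17.00000 nm, 90.00000 90.00000 90.00000 deg",
    "Reflections measured after indexing",
    "   h    k    l          I   sigma(I)       peak background  fs/px  ss/px panel",
    "  -3    1    2      55.50       7.70       60.00       5.00  120.0  220.0 q1",
    "End of reflections",
    "--- End crystal",
    "----- End chunk -----")
}
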