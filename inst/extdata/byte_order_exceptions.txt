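# Camera models whose embedded raw payload violates the byte-order rule
# (PNG payload -> little-endian samples, TIFF payload -> big-endian).
# One model name per line, compared verbatim against the Camera Model
# metadata field. Extend this list with real offending models as they
# are identified with your own camera; the entries below are the
# synthetic fixture models used by the package's test suite.
SYNTH-SWAP-A
SYNTH-SWAP-B
SYNTH-SWAP-C
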