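# Physicochemical properties of target PAHs.
# log_kow, mw and ring counts are literature defaults (Mackay et al.,
# Handbook of Physical-Chemical Properties, 2nd ed.; US EPA CompTox).
# These are configurable: results depend monotonically on log_kow, so users
# should supply their preferred property table via load_compound_registry().
name,n_rings,log_kow,mw
fluorene,3,4.18,166.22
anthracene,3,4.45,178.23
phenanthrene,3,4.46,178.23
pyrene,4,4.88,202.26
fluoranthene,4,5.16,202.26
benzo(a)anthracene,4,5.76,228.29
benzo(b)fluoranthene,5,5.78,252.31
chrysene,4,5.81,228.29
benzo(k)fluoranthene,5,6.11,252.31
benzo(a)pyrene,5,6.13,252.31
benzo(ghi)perylene,6,6.63,276.33
"indeno(1,2,3-cd)pyrene",6,6.70,276.33
"dibenzo(a,h)anthracene",5,6.75,278.35
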