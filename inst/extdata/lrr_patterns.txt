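# Default RI-like LRR consensus patterns.
# Class codes: L = {L,I,V}, S = {S,T}, E = {E,D,Q,N}, R = {R,K},
# o = nonpolar, g = Gly, x = any residue; [..] = literal residue set.
# Replace this file (see read_pattern_config) to use other consensus strings.

name type1
spec LxxLxLxxNxLxxLxgxLxSLxxExRxx
insertion NA

name type2
spec LxxLxLxxCxLxxLxxgxLxSLxxExRxx
insertion 16

name generic_RI
spec LxxLxLxx[NC]xLxxooxxLxxooxxxxxx
insertion NA
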