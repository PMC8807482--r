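# build with the system compiler toolchain
override CXX = g++
override CXX17 = g++
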