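# Use the system C++ toolchain: the shared object must load against the
# host C library at run time.
override CXX = g++
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
PKG_CXXFLAGS = -O3 -funroll-loops
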