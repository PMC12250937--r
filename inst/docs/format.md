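# The `.nsf` framed stream format

A byte-exact container for serially multiplexed multi-channel 16-bit
recordings, emulating a frame-synchronized acquisition loop. All
multi-byte fields are **little-endian**. Sample, headstage and channel
indices are 0-based.

## Header (16 bytes)

| offset | size | field             | value                          |
|--------|------|-------------------|--------------------------------|
| 0      | 4    | magic tag         | ASCII `NSF1`                   |
| 4      | 2    | version           | u16, `1`                       |
| 6      | 4    | fs_hz             | u32 sampling rate              |
| 10     | 1    | n_headstages      | u8, 1–8                        |
| 11     | 1    | n_channels_per_hs | u8, 1–16                       |
| 12     | 1    | payload_kind      | u8: 0 raw, 1 filtered + flags  |
| 13     | 3    | reserved          | zero bytes                     |

## Frame (one per sampling period)

| field       | size                  | value                                   |
|-------------|-----------------------|-----------------------------------------|
| sync word   | 8                     | u64 `0x5AFEC0DE5A17E5D1`                |
| frame index | 4                     | u32, informative only                   |
| samples     | 2 × n_hs × n_ch       | i16, serialization order (below)        |
| spike flags | ceil(n_hs × n_ch / 8) | only when payload_kind = 1              |

Serialization order is **channel-major**: position `p` carries
channel `p div n_hs` of headstage `p mod n_hs` — the acquisition loop
polls every headstage for one channel before moving to the next
channel. Flag bit `k` of flag byte `j` belongs to serialized position
`8·j + k`; a set bit means a spike was confirmed on that channel in
this frame (the detected peak is the channel's *previous* sample).

The sync word serialized little-endian is the byte sequence
`D1 E5 17 5A DE C0 FE 5A`.

## Worked example

One headstage, one channel, two raw frames with samples `5` and `−7`
(`0xFFF9` as i16):

```
offset  bytes                                            meaning
0x00    4E 53 46 31                                      "NSF1"
0x04    01 00                                            version 1
0x06    20 4E 00 00                                      fs = 20000
0x0A    01 01 00                                         1 hs, 1 ch, raw
0x0D    00 00 00                                         reserved
0x10    D1 E5 17 5A DE C0 FE 5A                          sync word
0x18    00 00 00 00                                      frame 0
0x1C    05 00                                            sample +5
0x1E    D1 E5 17 5A DE C0 FE 5A                          sync word
0x26    01 00 00 00                                      frame 1
0x2A    F9 FF                                            sample -7
```

Total: 16 + 2 × (8 + 4 + 2) = 44 bytes.

## Resynchronization

While synchronized, frame boundaries are trusted: sample bytes that
happen to mirror sync-word fragments can never cause a false resync.
If the 8 bytes at an expected frame boundary do not match the sync
word, the decoder enters `SEEK_SYNC`, scans byte-by-byte for the next
sync word (one *resync event* per corrupted region; skipped bytes are
counted and never emitted as samples) and resumes. A trailing region
holding a valid sync word but less than a full frame is a *partial
trailing frame*: dropped and counted, or carried over verbatim when
the caller streams the file in chunks.
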